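#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an annual carbon budget
#'
#' Bar chart of the annual budget terms per constituent (kgC ha^-1 yr^-1).
#'
#' @param object An [annual_budget()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.annual_budget <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              -dplyr::all_of("constituent"),
                              names_to = "term", values_to = "flux")
  long <- dplyr::filter(long, !is.na(.data$flux))
  long$term <- factor(long$term, levels = unique(long$term))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$term, y = .data$flux,
                                     fill = .data$constituent)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = expression(kgC ~ ha^-1 ~ yr^-1),
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot a sensitivity fit
#'
#' Parameters ordered by rank, bar height `-log10(p)`, with the significance
#' threshold marked.
#'
#' @param object A `sensitivity_fit` from [global_sensitivity()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sensitivity_fit <- function(object, ...) {
  tab <- object$table
  tab$term <- stats::reorder(tab$term, tab$rank)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$term,
                                    y = -log10(pmax(.data$p.value, 1e-300)),
                                    fill = .data$sensitive)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(object$alpha), linetype = 2) +
    ggplot2::labs(x = NULL, y = expression(-log[10](p)),
                  fill = paste0("p < ", object$alpha)) +
    ggplot2::theme_minimal()
}

#' Plot a daily forcing series
#'
#' Faceted time series of flow, temperature, sediment yield and the upland
#' carbon loads.
#'
#' @param forcing Daily forcing tibble.
#' @return A ggplot object.
#' @export
plot_forcing <- function(forcing) {
  forcing <- validate_forcing(forcing)
  long <- tidyr::pivot_longer(
    forcing[c("date", "flow", "temp", "sed_yield", "poc_load", "doc_load")],
    -dplyr::all_of("date"), names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$date, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
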