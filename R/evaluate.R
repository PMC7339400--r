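#' Align an observed/predicted pair of columns
#'
#' @noRd
paired_series_ <- function(data, observed, predicted, fn) {
  o <- rlang::eval_tidy(observed, data)
  p <- rlang::eval_tidy(predicted, data)
  if (length(o) != length(p)) {
    stop(fn, ": observed and predicted must have equal length", call. = FALSE)
  }
  if (length(o) < 2) {
    stop(fn, ": at least two paired values are required", call. = FALSE)
  }
  if (anyNA(o) || anyNA(p)) {
    stop(fn, ": missing values in the paired series", call. = FALSE)
  }
  list(o = as.numeric(o), p = as.numeric(p))
}

#' Nash-Sutcliffe model efficiency
#'
#' `NS = 1 - sum((o - p)^2) / sum((o - mean(o))^2)`. 1 is a perfect fit; 0
#' means the model predicts no better than the observed mean; negative values
#' are worse than the mean predictor. Requires non-constant observations.
#'
#' @param data Data frame holding the paired series.
#' @param observed,predicted Columns (bare names or expressions) of observed
#'   and predicted values.
#' @return Nash-Sutcliffe efficiency (unitless, <= 1).
#' @export
#' @examples
#' nash_sutcliffe(tibble::tibble(o = c(1, 2, 3), p = c(2, 2, 2)), o, p)
nash_sutcliffe <- function(data, observed = observed, predicted = predicted) {
  s <- paired_series_(data, rlang::enquo(observed), rlang::enquo(predicted),
                      "nash_sutcliffe")
  den <- sum((s$o - mean(s$o))^2)
  if (den == 0) {
    stop("nash_sutcliffe: observations are constant (zero variance)",
         call. = FALSE)
  }
  1 - sum((s$o - s$p)^2) / den
}

#' Percent bias
#'
#' `100 * (mean(o) - mean(p)) / mean(o)`: positive values mean the model
#' underestimates on average, negative values overestimation.
#'
#' @inheritParams nash_sutcliffe
#' @return Percent bias (%).
#' @export
#' @examples
#' pbias(tibble::tibble(o = c(2, 2), p = c(1.5, 1.5)), o, p)
pbias <- function(data, observed = observed, predicted = predicted) {
  s <- paired_series_(data, rlang::enquo(observed), rlang::enquo(predicted),
                      "pbias")
  if (mean(s$o) == 0) {
    stop("pbias: observed mean is zero", call. = FALSE)
  }
  100 * (mean(s$o) - mean(s$p)) / mean(s$o)
}

#' Model-performance summary for a paired series
#'
#' @inheritParams nash_sutcliffe
#' @return One-row tibble with `ns`, `pbias` and `n`.
#' @export
model_stats <- function(data, observed = observed, predicted = predicted) {
  tibble::tibble(
    ns = nash_sutcliffe(data, {{ observed }}, {{ predicted }}),
    pbias = pbias(data, {{ observed }}, {{ predicted }}),
    n = nrow(data)
  )
}

#' Aggregate daily values to calendar-month sums
#'
#' Sums the selected daily columns by calendar month; the standard
#' preprocessing before computing monthly Nash-Sutcliffe or percent bias on
#' loads.
#'
#' @param data Data frame with a `Date` column.
#' @param ... Columns to sum (tidyselect); defaults to every numeric column.
#' @param date Date column (bare name).
#' @return Tibble with `month` (first day of month, `Date`) and the summed
#'   columns.
#' @export
#' @examples
#' f <- generate_forcing(forcing_spec(n_days = 90, seed = 1))
#' aggregate_monthly(f, poc_load, doc_load)
aggregate_monthly <- function(data, ..., date = date) {
  d <- rlang::eval_tidy(rlang::enquo(date), data)
  d <- as.Date(d)
  sel <- rlang::enquos(...)
  data <- tibble::as_tibble(data)
  month <- as.Date(format(d, "%Y-%m-01"))
  if (length(sel) == 0) {
    keep <- vapply(data, is.numeric, logical(1))
    vals <- data[keep]
  } else {
    vals <- dplyr::select(data, !!!sel)
  }
  dplyr::summarise(
    dplyr::group_by(dplyr::bind_cols(tibble::tibble(month = month), vals),
                    month),
    dplyr::across(dplyr::everything(), sum),
    .groups = "drop"
  )
}

#' Monthly outlet loads of a simulation
#'
#' Convenience accessor: calendar-month sums of outlet POC (labile +
#' refractory), DOC (both source tags) and sediment loads.
#'
#' @param sim A `carbon_simulation`.
#' @return Tibble with `month`, `poc_kg`, `doc_kg`, `sed_kg`.
#' @export
monthly_outlet_loads <- function(sim) {
  d <- dplyr::mutate(sim$daily,
                     poc_kg = .data$out_lpoc + .data$out_rpoc,
                     doc_kg = .data$out_doc_alloch + .data$out_doc_autoch,
                     sed_kg = .data$out_sed)
  aggregate_monthly(d, poc_kg, doc_kg, sed_kg, date = date)
}
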