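# run fn with a temporary RNG state seeded by `seed`
with_seed_ <- function(seed, fn) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fn()
}

#' Latin hypercube sample of parameter values
#'
#' Stratified, seed-reproducible draw over the given parameter ranges: each
#' column has exactly one point per 1/k stratum of its range.
#'
#' @param ranges Named list of length-2 numeric ranges `c(min, max)`, or a
#'   data frame with columns `parameter`, `min`, `max`.
#' @param k Number of runs (rows).
#' @param seed Integer seed.
#' @return Tibble with `k` rows and one column per parameter.
#' @export
#' @examples
#' sample_parameters(list(v_lpoc = c(0.01, 1), spcon = c(1e-4, 0.01)),
#'                   k = 5, seed = 1)
sample_parameters <- function(ranges, k, seed = 1) {
  if (is.data.frame(ranges)) {
    ranges <- stats::setNames(
      purrr::map2(ranges$min, ranges$max, c), ranges$parameter)
  }
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  if (is.null(names(ranges)) || any(names(ranges) == "")) {
    stop("ranges must be named by parameter", call. = FALSE)
  }
  lo <- vapply(ranges, function(r) r[1], numeric(1))
  hi <- vapply(ranges, function(r) r[2], numeric(1))
  if (any(hi <= lo)) {
    stop("degenerate range(s): ",
         paste(names(ranges)[hi <= lo], collapse = ", "), call. = FALSE)
  }
  m <- length(ranges)
  u <- with_seed_(seed, function() lhs::randomLHS(as.integer(k), m))
  out <- purrr::map2(seq_len(m), names(ranges),
                     function(j, nm) lo[j] + u[, j] * (hi[j] - lo[j]))
  names(out) <- names(ranges)
  tibble::as_tibble(out)
}

#' Global sensitivity analysis by multiple regression
#'
#' Fits an ordinary-least-squares regression of an objective value (one per
#' model run, typically a Nash-Sutcliffe efficiency) on the sampled parameter
#' values, with intercept. Each parameter's two-sided t-test p-value measures
#' its influence; parameters are ranked by ascending p-value (rank 1 = most
#' sensitive) and flagged sensitive when `p < alpha`. A constant objective
#' carries no signal: every p-value is reported as 1 and nothing is flagged.
#'
#' @param data Data frame with one row per run: the sampled parameter columns
#'   plus the objective column.
#' @param objective Objective column (bare name); default `g`.
#' @param alpha Significance level for the sensitive flag.
#' @return A `sensitivity_fit` object; use [generics::tidy()] for the
#'   per-parameter table, [generics::glance()] for fit summaries.
#' @export
#' @examples
#' runs <- sample_parameters(list(a = c(0, 1), b = c(0, 1)), k = 30, seed = 1)
#' runs$g <- 2 * runs$a + rnorm(30, sd = 1e-3)
#' tidy(global_sensitivity(runs, g))
global_sensitivity <- function(data, objective = g, alpha = 0.05) {
  obj_q <- rlang::enquo(objective)
  g <- rlang::eval_tidy(obj_q, data)
  obj_name <- rlang::as_label(obj_q)
  params <- setdiff(names(data), obj_name)
  if (length(params) == 0) stop("no parameter columns found", call. = FALSE)
  b <- as.data.frame(data[params])
  k <- nrow(b); m <- ncol(b)
  if (k <= m + 1) {
    stop("need more runs than parameters + 1 (k > m + 1): k = ", k,
         ", m = ", m, call. = FALSE)
  }
  const_cols <- params[vapply(b, function(x) stats::sd(x) == 0, logical(1))]
  if (length(const_cols)) {
    stop("constant parameter column(s): ", paste(const_cols, collapse = ", "),
         call. = FALSE)
  }

  if (stats::sd(g) == 0) {
    tab <- tibble::tibble(
      term = params, estimate = 0, std.error = NA_real_, statistic = 0,
      p.value = 1, rank = rank(rep(1, m), ties.method = "first"),
      sensitive = FALSE
    )
    fit <- NULL
    r2 <- 0
  } else {
    df <- cbind(b, .g = g)
    fit <- stats::lm(.g ~ ., data = df)
    if (any(is.na(stats::coef(fit)))) {
      bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
      stop("rank-deficient design; collinear column(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    sm <- summary(fit)
    co <- sm$coefficients[params, , drop = FALSE]
    tab <- tibble::tibble(
      term = params,
      estimate = unname(co[, "Estimate"]),
      std.error = unname(co[, "Std. Error"]),
      statistic = unname(co[, "t value"]),
      p.value = unname(co[, "Pr(>|t|)"])
    )
    tab$rank <- rank(tab$p.value, ties.method = "first")
    tab$sensitive <- tab$p.value < alpha
    r2 <- sm$r.squared
  }
  structure(
    list(table = dplyr::arrange(tab, .data$rank), fit = fit, alpha = alpha,
         objective = obj_name, k = k, m = m, r.squared = r2),
    class = "sensitivity_fit"
  )
}

#' @export
print.sensitivity_fit <- function(x, ...) {
  cat("<sensitivity_fit> ", x$m, " parameters, ", x$k, " runs, objective ",
      x$objective, " (R^2 = ", signif(x$r.squared, 3), ")\n", sep = "")
  print(x$table)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname global_sensitivity
#' @param x A `sensitivity_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.sensitivity_fit <- function(x, ...) x$table

#' @rdname global_sensitivity
#' @exportS3Method generics::glance
glance.sensitivity_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r.squared, k = x$k, m = x$m,
                 n_sensitive = sum(x$table$sensitive),
                 alpha = x$alpha, objective = x$objective)
}

# apply named overrides to the routing/diagenesis parameter pair
override_params_ <- function(rparams, dparams, values) {
  for (nm in names(values)) {
    if (nm %in% names(rparams)) {
      rparams[[nm]] <- values[[nm]]
    } else if (nm %in% names(dparams)) {
      dparams[[nm]] <- values[[nm]]
    } else {
      stop("unknown parameter: ", nm, call. = FALSE)
    }
  }
  list(rparams = rparams, dparams = dparams)
}

#' Run the full sensitivity pipeline on a forcing series
#'
#' Draws a Latin hypercube sample over the given parameter ranges, simulates
#' the coupled reach/diagenesis model once per draw, scores each run by the
#' Nash-Sutcliffe efficiency of monthly outlet POC load against a reference
#' series, and fits the multiple-regression sensitivity model.
#'
#' @param forcing Daily forcing table.
#' @param ranges Parameter ranges (see [sample_parameters()]); names must be
#'   [routing_params()] or [diagenesis_params()] fields.
#' @param k Number of runs.
#' @param seed Integer seed for the hypercube draw.
#' @param reference Reference monthly POC loads (tibble with `month`,
#'   `poc_kg`); defaults to the run at the base parameter values.
#' @param rparams,dparams,geom,lgeom Base parameters passed to
#'   [run_simulation()].
#' @param alpha Significance level.
#' @return A `sensitivity_fit`; the per-run parameter/objective table is
#'   attached as `$runs`.
#' @export
run_sensitivity <- function(forcing, ranges, k = 100, seed = 1,
                            reference = NULL,
                            rparams = routing_params(),
                            dparams = diagenesis_params(),
                            geom = reach_geometry(),
                            lgeom = layer_geometry(),
                            alpha = 0.05) {
  forcing <- validate_forcing(forcing)
  if (is.null(reference)) {
    base <- run_simulation(forcing, dparams, rparams, geom, lgeom)
    reference <- monthly_outlet_loads(base)
  }
  draws <- sample_parameters(ranges, k, seed)
  g <- purrr::map_dbl(seq_len(k), function(i) {
    pars <- override_params_(rparams, dparams, as.list(draws[i, ]))
    sim <- run_simulation(forcing, pars$dparams, pars$rparams, geom, lgeom)
    pred <- monthly_outlet_loads(sim)
    nash_sutcliffe(
      dplyr::inner_join(reference, pred, by = "month",
                        suffix = c("_obs", "_sim")),
      observed = poc_kg_obs, predicted = poc_kg_sim
    )
  })
  runs <- dplyr::mutate(draws, g = g)
  fit <- global_sensitivity(runs, g, alpha = alpha)
  fit$runs <- runs
  fit
}

#' Recover parameters by grid search on Nash-Sutcliffe efficiency
#'
#' Scores every candidate parameter combination by the Nash-Sutcliffe
#' efficiency of monthly outlet POC load against an observed (or synthetic
#' truth) series and returns the grid ranked by fit. A simple identifiability
#' check: simulating with known parameters and re-fitting should place the
#' truth at the top of the grid.
#'
#' @param forcing Daily forcing table.
#' @param observed Monthly reference loads (tibble with `month`, `poc_kg`).
#' @param grid Data frame of candidate parameter combinations; column names
#'   must be [routing_params()] or [diagenesis_params()] fields.
#' @param rparams,dparams,geom,lgeom Base parameters.
#' @return The grid tibble with an `ns` column, sorted by decreasing `ns`;
#'   the best row first.
#' @export
calibrate_grid <- function(forcing, observed, grid,
                           rparams = routing_params(),
                           dparams = diagenesis_params(),
                           geom = reach_geometry(),
                           lgeom = layer_geometry()) {
  forcing <- validate_forcing(forcing)
  grid <- tibble::as_tibble(grid)
  ns <- purrr::map_dbl(seq_len(nrow(grid)), function(i) {
    pars <- override_params_(rparams, dparams, as.list(grid[i, ]))
    sim <- run_simulation(forcing, pars$dparams, pars$rparams, geom, lgeom)
    pred <- monthly_outlet_loads(sim)
    nash_sutcliffe(
      dplyr::inner_join(observed, pred, by = "month",
                        suffix = c("_obs", "_sim")),
      observed = poc_kg_obs, predicted = poc_kg_sim
    )
  })
  dplyr::arrange(dplyr::mutate(grid, ns = ns), dplyr::desc(ns))
}
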