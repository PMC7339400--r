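#' Watershed-normalized annual carbon budget
#'
#' Aggregates the daily fluxes of a simulation into average annual fluxes per
#' hectare of watershed, per constituent (POC and DOC): watershed (upland)
#' contribution, riverine (in-stream) contribution, outlet outflow, and for
#' POC the benthic terms — deposition, resuspension, net deposition, burial,
#' inorganic release and the accumulated sediment carbon residual.
#'
#' Unit convention: 1 kgC ha^-1 = 0.1 gC m^-2. The budget's
#' `inorganic_release` counts all inorganic carbon leaving the bed (methane
#' diffusion and bubbles, CO2 from methane oxidation, and the small
#' porewater-methane resuspension term) so that
#' `accumulated_sediment_c = deposition - resuspension - burial -
#' inorganic_release` (minus any denitrification sink) closes exactly on the
#' sediment storage change.
#'
#' @param sim A `carbon_simulation`, or its `daily` tibble.
#' @param area_ha Watershed area (ha); taken from the simulation when given.
#' @param years `"calendar-complete"` (default) averages only over calendar
#'   years fully covered by the series; `"all"` divides by the series length
#'   in years (n/365.25), including partial years.
#' @return An `annual_budget` tibble, one row per constituent, all flux
#'   columns in kgC ha^-1 yr^-1; the watershed area and the year mode are
#'   attached as attributes.
#' @export
#' @examples
#' f <- generate_forcing(forcing_spec(n_days = 365, seed = 1))
#' annual_budget(run_simulation(f), years = "all")
annual_budget <- function(sim, area_ha = NULL,
                          years = c("calendar-complete", "all")) {
  years <- match.arg(years)
  if (inherits(sim, "carbon_simulation")) {
    d <- sim$daily
    if (is.null(area_ha)) area_ha <- sim$area_ha
  } else {
    d <- tibble::as_tibble(sim)
  }
  if (is.null(area_ha) || area_ha <= 0) {
    stop("a positive watershed area (ha) is required", call. = FALSE)
  }

  if (years == "calendar-complete") {
    yr <- as.integer(format(d$date, "%Y"))
    days_in_year <- ifelse(yr %% 4 == 0 & (yr %% 100 != 0 | yr %% 400 == 0),
                           366L, 365L)
    keep <- yr %in% names(which(table(yr) == tapply(days_in_year, yr, max)))
    d <- d[keep, , drop = FALSE]
    if (nrow(d) == 0) {
      stop("no complete calendar years in the series; use years = \"all\"",
           call. = FALSE)
    }
    n_years <- length(unique(format(d$date, "%Y")))
  } else {
    n_years <- nrow(d) / 365.25
  }

  per_ha_yr <- function(x) sum(x) / area_ha / n_years
  poc <- tibble::tibble(
    constituent = "POC",
    watershed_contribution = per_ha_yr(d$poc_in_kg),
    riverine_contribution = per_ha_yr(d$algal_dep_kg),
    outlet_outflow = per_ha_yr(d$out_lpoc + d$out_rpoc),
    deposition = per_ha_yr(d$dep_poc_kg),
    resuspension = per_ha_yr(d$res_poc_kg),
    net_deposition = deposition - resuspension,
    burial = per_ha_yr(d$bury_kg),
    inorganic_release = per_ha_yr(d$inorg_kg),
    accumulated_sediment_c = deposition - resuspension - burial -
      inorganic_release - per_ha_yr(d$den_kg)
  )
  doc <- tibble::tibble(
    constituent = "DOC",
    watershed_contribution = per_ha_yr(d$doc_in_kg),
    riverine_contribution = per_ha_yr(d$doc_diss_kg + d$algal_doc_kg),
    outlet_outflow = per_ha_yr(d$out_doc_alloch + d$out_doc_autoch),
    deposition = NA_real_, resuspension = NA_real_,
    net_deposition = NA_real_, burial = NA_real_,
    inorganic_release = NA_real_, accumulated_sediment_c = NA_real_
  )
  out <- dplyr::bind_rows(poc, doc)
  attr(out, "watershed_area_ha") <- area_ha
  attr(out, "years") <- years
  class(out) <- c("annual_budget", class(out))
  out
}

#' Ratios between annual budget fluxes
#'
#' The standard diagnostic quotients of an annual budget: outlet outflow over
#' watershed contribution (Out/WC), net deposition over watershed
#' contribution and over outflow, resuspension over deposition, and burial
#' over watershed contribution, outflow and net deposition. A zero (or
#' missing) denominator yields `NA`, not an error.
#'
#' @param budget An [annual_budget()] tibble, or any data frame with columns
#'   `watershed_contribution`, `outlet_outflow` and (for the benthic ratios)
#'   `deposition`, `resuspension`, `burial`; `net_deposition` is derived when
#'   absent. An optional `constituent` column is carried through.
#' @param digits Optional number of significant digits for reporting; by
#'   default full precision is returned.
#' @return Tibble with columns `out_over_wc`, `ndep_over_wc`,
#'   `ndep_over_out`, `res_over_dep`, `bury_over_wc`, `bury_over_out`,
#'   `bury_over_ndep`.
#' @export
#' @examples
#' b <- tibble::tibble(constituent = "POC", watershed_contribution = 36.6,
#'                     outlet_outflow = 24.5, deposition = 11.44,
#'                     resuspension = 0.04, burial = 0.34)
#' ratio_table(b)
ratio_table <- function(budget, digits = NULL) {
  b <- tibble::as_tibble(budget)
  grab <- function(col) {
    if (col %in% names(b)) b[[col]] else rep(NA_real_, nrow(b))
  }
  wc <- grab("watershed_contribution")
  out <- grab("outlet_outflow")
  dep <- grab("deposition")
  res <- grab("resuspension")
  bury <- grab("burial")
  ndep <- grab("net_deposition")
  ndep <- ifelse(is.na(ndep), dep - res, ndep)

  div <- function(num, den) ifelse(is.na(den) | den == 0, NA_real_, num / den)
  r <- tibble::tibble(
    out_over_wc = div(out, wc),
    ndep_over_wc = div(ndep, wc),
    ndep_over_out = div(ndep, out),
    res_over_dep = div(res, dep),
    bury_over_wc = div(bury, wc),
    bury_over_out = div(bury, out),
    bury_over_ndep = div(bury, ndep)
  )
  if (!is.null(digits)) r <- dplyr::mutate(r, dplyr::across(
    dplyr::everything(), ~ signif(.x, digits)))
  if ("constituent" %in% names(b)) {
    r <- dplyr::bind_cols(tibble::tibble(constituent = b$constituent), r)
  }
  r
}

#' Benthic budget: fate of deposited organic carbon
#'
#' Expresses the fate of total organic carbon deposited on the riverbed as
#' percentages: resuspended back to the water column, buried out of the
#' system, released as inorganic carbon (CH4 + CO2), and the residual that
#' accumulates in the sediment. The four percentages sum to 100 before
#' rounding. Deposition of zero yields missing values.
#'
#' @param budget A data frame with columns `deposition`, `resuspension`,
#'   `burial`, `inorganic_release` (kgC ha^-1 yr^-1); rows without a positive
#'   deposition (e.g. DOC) return `NA`s. Scalars may be passed via a one-row
#'   tibble.
#' @return Tibble with the four flux columns (kgC ha^-1 yr^-1),
#'   `accumulated_sediment_c` as the residual, and percentage columns
#'   `pct_resuspension`, `pct_burial`, `pct_inorganic`, `pct_accumulated`.
#' @export
#' @examples
#' benthic_budget(tibble::tibble(deposition = 11.5, resuspension = 0.04,
#'                               burial = 0.34, inorganic_release = 9.05))
benthic_budget <- function(budget) {
  b <- tibble::as_tibble(budget)
  need <- c("deposition", "resuspension", "burial", "inorganic_release")
  missing_c <- setdiff(need, names(b))
  if (length(missing_c)) {
    stop("budget is missing column(s): ", paste(missing_c, collapse = ", "),
         call. = FALSE)
  }
  dep <- b$deposition
  ok <- !is.na(dep) & dep > 0
  accum <- dep - b$resuspension - b$burial - b$inorganic_release
  pct <- function(x) ifelse(ok, 100 * x / dep, NA_real_)
  out <- tibble::tibble(
    deposition = dep,
    resuspension = b$resuspension,
    burial = b$burial,
    inorganic_release = b$inorganic_release,
    accumulated_sediment_c = ifelse(ok, accum, NA_real_),
    pct_resuspension = pct(b$resuspension),
    pct_burial = pct(b$burial),
    pct_inorganic = pct(b$inorganic_release),
    pct_accumulated = pct(accum)
  )
  if ("constituent" %in% names(b)) {
    out <- dplyr::bind_cols(tibble::tibble(constituent = b$constituent), out)
  }
  out
}
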