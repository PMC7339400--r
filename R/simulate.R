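#' Validate a daily forcing table
#'
#' Checks the schema of a daily forcing table: required columns, nonnegative
#' values, strictly increasing gap-free daily dates.
#'
#' @param forcing A data frame with columns `date`, `flow`, `velocity`,
#'   `depth`, `temp`, `sed_yield`, `poc_load`, `doc_load` and optionally
#'   `algal_debris` (gC m^-2 day^-1, defaulting to 0).
#' @return The forcing as a tibble with `algal_debris` filled in.
#' @export
validate_forcing <- function(forcing) {
  need <- c("date", "flow", "velocity", "depth", "temp", "sed_yield",
            "poc_load", "doc_load")
  missing_c <- setdiff(need, names(forcing))
  if (length(missing_c)) {
    stop("forcing is missing column(s): ", paste(missing_c, collapse = ", "),
         call. = FALSE)
  }
  forcing <- tibble::as_tibble(forcing)
  if (!"algal_debris" %in% names(forcing)) forcing$algal_debris <- 0
  d <- as.Date(forcing$date)
  if (nrow(forcing) > 1 && any(diff(d) != 1)) {
    gap <- which(diff(d) != 1)[1]
    stop("forcing dates must be gap-free daily; problem after ", d[gap],
         call. = FALSE)
  }
  num <- c("flow", "velocity", "depth", "temp", "sed_yield", "poc_load",
           "doc_load", "algal_debris")
  vals <- as.matrix(forcing[setdiff(num, "temp")])
  if (anyNA(forcing[num]) || any(vals < 0)) {
    stop("forcing values must be present and nonnegative", call. = FALSE)
  }
  forcing$date <- d
  forcing
}

#' Simulate coupled reach routing and sediment diagenesis
#'
#' Runs the daily loop over a forcing series: upland loads enter the
#' well-mixed reach, suspended sediment exchanges with the bed by the
#' transport-capacity rule, POC settles onto the bed and drives the two-layer
#' diagenesis model, and benthic resuspension returns carbon to the
#' refractory POC pool with a one-day lag. The run is fully deterministic
#' given the forcing and parameters.
#'
#' @param forcing Daily forcing table (see [validate_forcing()]); typically
#'   from [generate_forcing()].
#' @param dparams A [diagenesis_params()].
#' @param rparams A [routing_params()].
#' @param geom A [reach_geometry()].
#' @param lgeom A [layer_geometry()].
#' @param area_ha Watershed area (ha) used for budget normalization.
#' @param init_wc,init_sed Initial [water_column_state()] and
#'   [sediment_state()].
#' @param bed_store Initial erodible bed sediment store (g m^-2).
#' @return A `carbon_simulation` object: list with `daily` (tibble of states,
#'   interface fluxes in gC m^-2 day^-1 and daily loads in kg day^-1),
#'   `final`, `area_ha`, `geom` and the parameter sets.
#' @export
#' @examples
#' f <- generate_forcing(forcing_spec(n_days = 30, seed = 1))
#' sim <- run_simulation(f)
#' sim
run_simulation <- function(forcing,
                           dparams = diagenesis_params(),
                           rparams = routing_params(),
                           geom = reach_geometry(),
                           lgeom = layer_geometry(),
                           area_ha = 22070,
                           init_wc = water_column_state(),
                           init_sed = sediment_state(),
                           bed_store = 0) {
  forcing <- validate_forcing(forcing)
  n <- nrow(forcing)
  area <- geom$area
  wc <- init_wc
  sed <- init_sed
  pending_return <- 0      # gC day^-1, benthic resuspension in transit
  prev_depth <- forcing$depth[1]
  init_storage_kg <- wc_carbon_kg_(wc, area, prev_depth) +
    sediment_carbon_kg_(sed, area, lgeom)
  init_sed_mineral_kg <- (wc$sed * area * prev_depth + bed_store * area) / 1000

  flux_names <- c("j_poc_dep_g1", "j_poc_dep_g2", "j_poc_dep_g3",
                  "j_poc_res_g1", "j_poc_res_g2", "j_poc_res_g3",
                  "j_poc_min_g1", "j_poc_min_g2", "j_poc_min_g3",
                  "j_poc_bury_g1", "j_poc_bury_g2", "j_poc_bury_g3",
                  "j_c", "j_c_den", "j_ch4_d", "j_ch4_gas",
                  "j_ch4_w", "j_ch4_r", "j_ch4_o")
  fx <- matrix(0, n, length(flux_names), dimnames = list(NULL, flux_names))
  cols <- c("lpoc", "rpoc", "doc_alloch", "doc_autoch", "sed_conc",
            "poc_g1", "poc_g2", "poc_g3", "ch4", "bed_store",
            "j_sed_r", "sed_deposition",
            "out_lpoc", "out_rpoc", "out_doc_alloch", "out_doc_autoch",
            "out_sed", "dep_poc_kg", "res_poc_kg", "bury_kg", "inorg_kg",
            "den_kg", "doc_diss_kg", "doc_min_kg", "algal_dep_kg")
  st <- matrix(0, n, length(cols), dimnames = list(NULL, cols))

  for (i in seq_len(n)) {
    day <- forcing[i, ]
    rr <- step_reach(wc, day, rparams, geom, bed_store = bed_store,
                     rpoc_return = pending_return, prev_depth = prev_depth)
    wc <- rr$state
    bed_store <- rr$bed_store
    prev_depth <- day$depth

    j_settled <- rr$j_settle_lpoc + rr$j_settle_rpoc + day$algal_debris
    dg <- diagenesis_step(sed, j_settled, rr$j_sed_r, day$temp,
                          dparams, lgeom)
    sed <- dg$state
    f <- dg$fluxes
    fx[i, ] <- f[flux_names]

    res_poc <- f[["j_poc_res_g1"]] + f[["j_poc_res_g2"]] + f[["j_poc_res_g3"]]
    pending_return <- res_poc * area        # gC day^-1, enters tomorrow

    st[i, ] <- c(
      wc$lpoc, wc$rpoc, wc$doc_alloch, wc$doc_autoch, wc$sed,
      sed$poc_g1, sed$poc_g2, sed$poc_g3, sed$ch4, bed_store,
      rr$j_sed_r, rr$sed_deposition,
      rr$outlet[["lpoc"]], rr$outlet[["rpoc"]], rr$outlet[["doc_alloch"]],
      rr$outlet[["doc_autoch"]], rr$outlet[["sed"]],
      j_settled * area / 1000,
      res_poc * area / 1000,
      (f[["j_poc_bury_g1"]] + f[["j_poc_bury_g2"]] + f[["j_poc_bury_g3"]]) *
        area / 1000,
      (f[["j_ch4_w"]] + f[["j_ch4_gas"]] + f[["j_ch4_o"]] + f[["j_ch4_r"]]) *
        area / 1000,
      f[["j_c_den"]] * area / 1000,
      rr$doc_dissolution, rr$doc_mineralized,
      day$algal_debris * area / 1000
    )
  }

  daily <- dplyr::bind_cols(
    tibble::tibble(date = forcing$date,
                   depth = forcing$depth,
                   flow = forcing$flow,
                   poc_in_kg = forcing$poc_load,
                   doc_in_kg = forcing$doc_load,
                   sed_in_mg = forcing$sed_yield,
                   algal_doc_kg = rparams$algal_doc),
    tibble::as_tibble(st),
    tibble::as_tibble(fx)
  )
  structure(
    list(daily = daily,
         final = list(water_column = wc, sediment = sed,
                      bed_store = bed_store,
                      pending_return_kg = pending_return / 1000,
                      depth = prev_depth),
         init_storage_kg = init_storage_kg,
         init_sed_mineral_kg = init_sed_mineral_kg,
         area_ha = area_ha, geom = geom, lgeom = lgeom,
         dparams = dparams, rparams = rparams),
    class = "carbon_simulation"
  )
}

# organic carbon held in the water column (kg)
wc_carbon_kg_ <- function(wc, area, depth) {
  (wc$lpoc + wc$rpoc + wc$doc_alloch + wc$doc_autoch) * area * depth / 1000
}

# organic carbon + methane held in the sediment layers (kg)
sediment_carbon_kg_ <- function(sed, area, lgeom) {
  ((sed$poc_g1 + sed$poc_g2 + sed$poc_g3) * lgeom$h2 +
     sed$ch4 * lgeom$h1) * area / 1000
}

#' @export
print.carbon_simulation <- function(x, ...) {
  d <- x$daily
  cat("<carbon_simulation> ", nrow(d), " days (", format(min(d$date)), " to ",
      format(max(d$date)), ")\n", sep = "")
  cat("  reach ", x$geom$length / 1000, " km x ", x$geom$width,
      " m; watershed ", x$area_ha, " ha\n", sep = "")
  bal <- carbon_balance(x)
  cat("  cumulative C in ", signif(bal$total_in, 4), " kg, out ",
      signif(bal$total_out, 4), " kg, stored ",
      signif(bal$delta_storage, 4),
      " kg (relative closure error ", format(bal$rel_error, digits = 3),
      ")\n", sep = "")
  invisible(x)
}

#' Whole-system carbon balance of a simulation
#'
#' Cumulative check that every gram of organic carbon entering the system
#' (upland POC and DOC, algal debris, algal-mortality DOC) is accounted for
#' by outlet export, burial, inorganic release, denitrification and
#' water-column DOC mineralization, plus the change in storage (water column,
#' sediment pools, aerobic methane, and resuspended carbon in transit back to
#' the water column).
#'
#' @param sim A `carbon_simulation`.
#' @return One-row tibble with `total_in`, `total_out`, `delta_storage` (kgC)
#'   and the relative closure error `rel_error`.
#' @export
carbon_balance <- function(sim) {
  d <- sim$daily
  total_in <- sum(d$poc_in_kg) + sum(d$doc_in_kg) + sum(d$algal_dep_kg) +
    sum(d$algal_doc_kg)
  total_out <- sum(d$out_lpoc) + sum(d$out_rpoc) + sum(d$out_doc_alloch) +
    sum(d$out_doc_autoch) + sum(d$bury_kg) + sum(d$inorg_kg) +
    sum(d$den_kg) + sum(d$doc_min_kg)
  fin <- sim$final
  end_storage <- wc_carbon_kg_(fin$water_column, sim$geom$area, fin$depth) +
    sediment_carbon_kg_(fin$sediment, sim$geom$area, sim$lgeom) +
    fin$pending_return_kg
  delta_storage <- end_storage - sim$init_storage_kg
  rel <- (total_in - total_out - delta_storage) /
    max(total_in, end_storage, 1e-12)
  tibble::tibble(total_in = total_in, total_out = total_out,
                 delta_storage = delta_storage, rel_error = rel)
}

#' Mineral sediment mass balance of a simulation
#'
#' Companion check to [carbon_balance()] for suspended/bed sediment: upland
#' sediment input equals outlet export plus the change in suspended and
#' bed-store mass.
#'
#' @param sim A `carbon_simulation`.
#' @return One-row tibble with `total_in`, `total_out`, `delta_storage` (kg)
#'   and `rel_error`.
#' @export
sediment_balance <- function(sim) {
  d <- sim$daily
  area <- sim$geom$area
  total_in <- sum(d$sed_in_mg) * 1000                       # Mg -> kg
  total_out <- sum(d$out_sed)
  fin <- sim$final
  end_storage <- (fin$water_column$sed * area * fin$depth +
                    fin$bed_store * area) / 1000
  delta_storage <- end_storage - sim$init_sed_mineral_kg
  rel <- (total_in - total_out - delta_storage) /
    max(total_in, end_storage, 1e-12)
  tibble::tibble(total_in = total_in, total_out = total_out,
                 delta_storage = delta_storage, rel_error = rel)
}
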