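#' Upland particulate organic carbon load from eroded sediment
#'
#' Eroded sediment carries organic carbon enriched relative to the source
#' topsoil: `sed_yield * 1000 * soc_frac * er_poc`.
#'
#' @param sed_yield Upland sediment yield (Mg ha^-1).
#' @param soc_frac Organic carbon fraction of the soil surface layer
#'   (gC per g soil).
#' @param er_poc POC enrichment ratio (POC concentration in eroded sediment
#'   over organic carbon concentration in source topsoil).
#' @return POC load (kgC ha^-1) on the same time basis as `sed_yield`.
#' @export
#' @examples
#' upland_poc_load(1, soc_frac = 0.01, er_poc = 2.98)
upland_poc_load <- function(sed_yield, soc_frac, er_poc) {
  if (any(c(sed_yield, soc_frac, er_poc) < 0)) {
    stop("upland load inputs must be nonnegative", call. = FALSE)
  }
  sed_yield * 1000 * soc_frac * er_poc
}

#' Maximum sediment transport capacity of the reach
#'
#' Simplified Bagnold stream-power form: `spcon * (prf * velocity)^spexp`.
#' The result carries whatever concentration unit `spcon` embodies; with the
#' conventional calibration (`spcon` on the order of 1e-3) the capacity is in
#' Mg sediment per m^3 of water, and [step_reach()] converts it to g m^-3
#' with the fixed factor 1e6 g/Mg.
#'
#' @param velocity Channel flow velocity (m s^-1).
#' @param params A [routing_params()].
#' @return Transport capacity concentration, in the units `spcon` carries.
#' @export
#' @examples
#' max_sediment_conc(1, routing_params())
max_sediment_conc <- function(velocity, params = routing_params()) {
  if (velocity < 0) stop("velocity must be nonnegative", call. = FALSE)
  params$spcon * (params$prf * velocity)^params$spexp
}

#' Exchange suspended sediment with the bed
#'
#' Capacity-rule exchange: suspended sediment above the transport capacity
#' settles to the bed within the step; below capacity, the deficit is
#' resuspended, limited by the bed sediment store. Exactly one of deposition
#' and resuspension is nonzero.
#'
#' @param sed_conc Suspended sediment concentration (g m^-3).
#' @param max_conc Transport capacity (g m^-3).
#' @param bed_store Erodible bed sediment store (g m^-2).
#' @param depth Water depth (m).
#' @param dt Step length (day).
#' @return List with `sed_conc` (g m^-3), `deposition` and `j_sed_r`
#'   (both g m^-2 day^-1) and `bed_store` (g m^-2).
#' @export
sediment_exchange <- function(sed_conc, max_conc, bed_store, depth, dt = 1) {
  if (any(c(sed_conc, max_conc, bed_store, depth) < 0) || dt <= 0) {
    stop("sediment exchange inputs must be nonnegative (dt positive)",
         call. = FALSE)
  }
  if (sed_conc > max_conc) {
    dep <- (sed_conc - max_conc) * depth / dt
    list(sed_conc = max_conc, deposition = dep, j_sed_r = 0,
         bed_store = bed_store + dep * dt)
  } else {
    j_r <- min((max_conc - sed_conc) * depth / dt, bed_store / dt)
    list(sed_conc = sed_conc + j_r * dt / depth, deposition = 0,
         j_sed_r = j_r, bed_store = bed_store - j_r * dt)
  }
}

#' Particulate organic carbon settling flux
#'
#' @param conc POC concentration in the water column (gC m^-3).
#' @param v_settle Settling velocity (m day^-1).
#' @return Settling flux (gC m^-2 day^-1).
#' @export
#' @examples
#' poc_settling_flux(1, 0.12)
poc_settling_flux <- function(conc, v_settle) {
  if (conc < 0 || v_settle < 0) {
    stop("settling inputs must be nonnegative", call. = FALSE)
  }
  v_settle * conc
}

# Exact one-step update of a completely mixed pool with pulse input and
# competing first-order losses: M1 = (M0 + L*dt) * exp(-lambda*dt); the mass
# removed is split among pathways in proportion to their rates, so the
# balance closes exactly and the CSTR steady state out = in / (1 + r_i/flush)
# is reproduced at any dt.
linear_pool_step_ <- function(mass0, input, rates, dt) {
  lam <- sum(rates)
  m <- mass0 + input * dt
  if (lam <= 0) {
    return(list(mass = m, removed = stats::setNames(numeric(length(rates)),
                                                    names(rates))))
  }
  removed_total <- m * (1 - exp(-lam * dt))
  list(mass = m - removed_total,
       removed = removed_total * rates / lam)
}

#' Advance the well-mixed reach one day
#'
#' Completely-mixed-reactor balance for suspended sediment, labile and
#' refractory POC, and source-tagged DOC. Upland loads enter as a start-of-day
#' pulse; sediment exchanges with the bed by the capacity rule
#' ([sediment_exchange()]); each carbon pool then loses mass to outflow and
#' its first-order pathways (settling, dissolution, mineralization) via an
#' exact linear-reservoir update. POC dissolution and any algal-mortality
#' source feed the autochthonous DOC tag; allochthonous DOC never migrates
#' tags.
#'
#' @param state A [water_column_state()].
#' @param forcing_day One row of a daily forcing table (list-like) with
#'   `flow` (m^3 s^-1), `velocity` (m s^-1), `depth` (m), `temp` (degC),
#'   `sed_yield` (Mg day^-1), `poc_load` (kgC day^-1), `doc_load`
#'   (kgC day^-1).
#' @param params A [routing_params()].
#' @param geom A [reach_geometry()].
#' @param bed_store Erodible bed sediment store (g m^-2).
#' @param rpoc_return Resuspended bed organic carbon returned to the
#'   refractory POC pool (gC day^-1), normally the previous day's benthic
#'   resuspension.
#' @param prev_depth Depth (m) at which the incoming `state` concentrations
#'   were formed. Water mass is conserved when depth changes between days:
#'   start-of-day masses are `conc * area * prev_depth`, and the returned
#'   concentrations refer to today's volume. Defaults to today's depth.
#' @param dt Step length (day).
#' @return List with `state` (new [water_column_state()]), `bed_store`,
#'   `j_sed_r` and `sed_deposition` (g m^-2 day^-1), settling fluxes
#'   `j_settle_lpoc`/`j_settle_rpoc` (gC m^-2 day^-1), `outlet` (named
#'   vector of outlet loads, kg day^-1, by constituent and source tag),
#'   `doc_dissolution` and `doc_mineralized` (kgC day^-1).
#' @export
step_reach <- function(state, forcing_day, params = routing_params(),
                       geom = reach_geometry(), bed_store = 0,
                       rpoc_return = 0, prev_depth = NULL, dt = 1) {
  need <- c("flow", "velocity", "depth", "temp", "sed_yield", "poc_load",
            "doc_load")
  forcing_day <- as.list(forcing_day)
  missing_f <- setdiff(need, names(forcing_day))
  if (length(missing_f)) {
    stop("forcing day is missing field(s): ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  }
  depth <- forcing_day$depth
  if (depth <= 0) stop("depth must be positive", call. = FALSE)
  area <- geom$area
  vol <- area * depth
  vol0 <- area * (if (is.null(prev_depth)) depth else prev_depth)
  q_day <- forcing_day$flow * 86400            # m^3 day^-1
  flush <- q_day / vol                          # day^-1

  ## suspended sediment: pulse load, capacity exchange, then flushing
  sed_conc <- (state$sed * vol0 + forcing_day$sed_yield * 1e6) / vol
  cmx <- 1e6 * max_sediment_conc(forcing_day$velocity, params)  # Mg/m3 -> g/m3
  ex <- sediment_exchange(sed_conc, cmx, bed_store, depth, dt)
  sed_step <- linear_pool_step_(ex$sed_conc * vol, 0, c(out = flush), dt)

  ## POC pools (gC): outflow + settling + dissolution
  l_lpoc <- params$lpoc_frac * forcing_day$poc_load * 1000
  l_rpoc <- (1 - params$lpoc_frac) * forcing_day$poc_load * 1000 + rpoc_return
  rates_l <- c(out = flush, settle = params$v_lpoc / depth,
               diss = params$k_poc_diss)
  rates_r <- c(out = flush, settle = params$v_rpoc / depth,
               diss = params$k_poc_diss)
  lpoc <- linear_pool_step_(state$lpoc * vol0, l_lpoc, rates_l, dt)
  rpoc <- linear_pool_step_(state$rpoc * vol0, l_rpoc, rates_r, dt)

  ## DOC tags (gC): outflow + mineralization; autochthonous gains dissolution
  rates_doc <- c(out = flush, min = params$k_doc_min)
  diss_total <- lpoc$removed[["diss"]] + rpoc$removed[["diss"]]
  doc_a <- linear_pool_step_(state$doc_alloch * vol0,
                             forcing_day$doc_load * 1000, rates_doc, dt)
  doc_u <- linear_pool_step_(state$doc_autoch * vol0,
                             diss_total / dt + params$algal_doc * 1000,
                             rates_doc, dt)

  new_state <- water_column_state(
    lpoc = lpoc$mass / vol, rpoc = rpoc$mass / vol,
    doc_alloch = doc_a$mass / vol, doc_autoch = doc_u$mass / vol,
    sed = sed_step$mass / vol
  )
  outlet <- c(
    lpoc = lpoc$removed[["out"]], rpoc = rpoc$removed[["out"]],
    doc_alloch = doc_a$removed[["out"]], doc_autoch = doc_u$removed[["out"]],
    sed = sed_step$removed[["out"]]
  ) / 1000 / dt                                 # g -> kg day^-1

  list(
    state = new_state,
    bed_store = ex$bed_store,
    j_sed_r = ex$j_sed_r,
    sed_deposition = ex$deposition,
    j_settle_lpoc = lpoc$removed[["settle"]] / area / dt,
    j_settle_rpoc = rpoc$removed[["settle"]] / area / dt,
    outlet = outlet,
    doc_dissolution = diss_total / 1000 / dt,
    doc_mineralized = (doc_a$removed[["min"]] + doc_u$removed[["min"]]) / 1000 / dt
  )
}
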