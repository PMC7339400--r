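#' Split settled organic carbon into reactivity fractions
#'
#' Organic carbon settling onto the bed is partitioned into the labile (G1),
#' slow-reacting (G2) and non-reacting (G3) pools of the anaerobic layer in
#' fixed proportions `f_g1`, `f_g2`, `f_g3`.
#'
#' @param j_total Total settled organic carbon flux (gC m^-2 day^-1).
#' @param params A [diagenesis_params()] object.
#' @return Named numeric vector `c(g1, g2, g3)` of per-pool deposition fluxes
#'   (gC m^-2 day^-1); the components sum to `j_total`.
#' @export
#' @examples
#' partition_deposition(1, diagenesis_params())
partition_deposition <- function(j_total, params = diagenesis_params()) {
  if (!is.numeric(j_total) || length(j_total) != 1 || is.na(j_total)) {
    stop("j_total must be a single number", call. = FALSE)
  }
  if (j_total < 0) stop("settled carbon flux cannot be negative", call. = FALSE)
  c(g1 = params$f_g1 * j_total,
    g2 = params$f_g2 * j_total,
    g3 = params$f_g3 * j_total)
}

# Porewater/particulate carbon carried off the bed with resuspended sediment:
# concentration over bulk bed density (converted Mg -> g) times the sediment
# resuspension flux, capped so no more carbon leaves than the pool holds.
resuspension_flux_ <- function(conc, rho_sed, j_sed_r, available_mass, dt) {
  if (rho_sed <= 0) stop("rho_sed must be positive", call. = FALSE)
  if (any(c(conc, j_sed_r, available_mass, dt) < 0)) {
    stop("resuspension inputs must be nonnegative", call. = FALSE)
  }
  min(conc / (rho_sed * 1e6) * j_sed_r, available_mass / dt)
}

#' Particulate organic carbon resuspension flux
#'
#' Carbon returned to the water column with resuspended bed sediment. The raw
#' flux is `poc_gi / (rho_sed * 1e6) * j_sed_r`; it is limited so the pool
#' cannot lose more mass than it holds over the step.
#'
#' @param poc_gi Pool concentration in the anaerobic layer (gC m^-3).
#' @param rho_sed Bed sediment density (Mg m^-3).
#' @param j_sed_r Resuspended bed-sediment mass flux (g m^-2 day^-1).
#' @param available_mass Areal carbon mass available in the pool (gC m^-2).
#' @param dt Step length (day).
#' @return Resuspension flux (gC m^-2 day^-1).
#' @export
#' @examples
#' poc_resuspension_flux(1000, 1.0, 1000, available_mass = 100)
poc_resuspension_flux <- function(poc_gi, rho_sed, j_sed_r,
                                  available_mass = Inf, dt = 1) {
  resuspension_flux_(poc_gi, rho_sed, j_sed_r, available_mass, dt)
}

#' Methane resuspension flux
#'
#' Dissolved methane carried out of the aerobic layer with resuspended
#' sediment; same form and mass limiter as [poc_resuspension_flux()].
#'
#' @param ch4 Dissolved CH4 concentration in the aerobic layer (gC m^-3).
#' @inheritParams poc_resuspension_flux
#' @return Resuspension flux (gC m^-2 day^-1).
#' @export
ch4_resuspension_flux <- function(ch4, rho_sed, j_sed_r,
                                  available_mass = Inf, dt = 1) {
  resuspension_flux_(ch4, rho_sed, j_sed_r, available_mass, dt)
}

#' Mineralization flux of a sediment organic carbon pool
#'
#' First-order decay with Arrhenius-style temperature correction, integrated
#' over the anaerobic layer: `k * theta^(T - 20) * poc * H2`. The non-reacting
#' G3 pool never mineralizes.
#'
#' @param poc_gi Pool concentration (gC m^-3).
#' @param k_gi First-order rate at 20 degC (day^-1).
#' @param theta_gi Temperature base.
#' @param temp_c Sediment (= overlying water) temperature (degC).
#' @param h2 Anaerobic-layer thickness (m).
#' @param pool Which pool: `"g1"`, `"g2"` or `"g3"`. `"g3"` returns 0
#'   regardless of the other inputs.
#' @return Mineralization flux (gC m^-2 day^-1).
#' @export
#' @examples
#' poc_mineralization_flux(100, 0.035, 1.1, temp_c = 20, h2 = 0.1)
poc_mineralization_flux <- function(poc_gi, k_gi, theta_gi, temp_c, h2,
                                    pool = c("g1", "g2", "g3")) {
  pool <- match.arg(pool)
  if (pool == "g3") return(0)
  if (any(c(poc_gi, k_gi, theta_gi, h2) < 0)) {
    stop("mineralization inputs must be nonnegative", call. = FALSE)
  }
  k_gi * theta_gi^(temp_c - 20) * poc_gi * h2
}

#' Burial flux of a sediment organic carbon pool
#'
#' Permanent loss below the active layers at the burial velocity:
#' `w_bury * poc_gi`.
#'
#' @param poc_gi Pool concentration (gC m^-3).
#' @param w_bury Burial velocity (m day^-1).
#' @return Burial flux (gC m^-2 day^-1).
#' @export
#' @examples
#' poc_burial_flux(1000, 6.85e-6)
poc_burial_flux <- function(poc_gi, w_bury) {
  if (poc_gi < 0 || w_bury < 0) {
    stop("burial inputs must be nonnegative", call. = FALSE)
  }
  w_bury * poc_gi
}

#' Advance the anaerobic organic carbon pools one step
#'
#' Explicit-Euler update of the G1/G2/G3 mass balance in the anaerobic layer:
#' deposition in; resuspension, mineralization (G1/G2 only) and burial out.
#' If the summed sinks would exceed the pool's mass plus the step's
#' deposition, all sinks are rescaled proportionally so the pool bottoms out
#' at exactly zero — mass is conserved and never goes negative.
#'
#' @param state A [sediment_state()].
#' @param dep Named per-pool deposition fluxes as returned by
#'   [partition_deposition()] (gC m^-2 day^-1).
#' @param j_sed_r Resuspended bed-sediment mass flux (g m^-2 day^-1).
#' @param temp_c Temperature (degC).
#' @param params A [diagenesis_params()].
#' @param geom A [layer_geometry()].
#' @param dt Step length (day).
#' @return List with `state` (updated [sediment_state()]; `ch4` untouched)
#'   and `fluxes`, a named numeric vector of the per-pool deposition,
#'   resuspension, mineralization and burial fluxes plus the diagenesis flux
#'   `j_c = j_poc_min_g1 + j_poc_min_g2` (all gC m^-2 day^-1).
#' @export
step_anaerobic <- function(state, dep, j_sed_r, temp_c,
                           params = diagenesis_params(),
                           geom = layer_geometry(), dt = 1) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  h2 <- geom$h2
  pools <- c("g1", "g2", "g3")
  ks <- c(params$k_g1, params$k_g2, 0)
  thetas <- c(params$theta_g1, params$theta_g2, 1)
  conc <- c(state$poc_g1, state$poc_g2, state$poc_g3)

  res <- min_ <- bury <- new_conc <- numeric(3)
  for (i in seq_along(pools)) {
    j_res <- poc_resuspension_flux(conc[i], params$rho_sed, j_sed_r,
                                   available_mass = conc[i] * h2, dt = dt)
    j_min <- poc_mineralization_flux(conc[i], ks[i], thetas[i], temp_c, h2,
                                     pool = pools[i])
    j_bury <- poc_burial_flux(conc[i], params$w_bury)
    sinks <- j_res + j_min + j_bury
    avail <- conc[i] * h2 + dep[[i]] * dt
    if (sinks * dt > avail && sinks > 0) {
      scale <- avail / (sinks * dt)
      j_res <- j_res * scale; j_min <- j_min * scale; j_bury <- j_bury * scale
    }
    res[i] <- j_res; min_[i] <- j_min; bury[i] <- j_bury
    new_conc[i] <- max(0, conc[i] + dt / h2 * (dep[[i]] - j_res - j_min - j_bury))
  }

  fl <- c(
    stats::setNames(as.numeric(dep[1:3]), paste0("j_poc_dep_", pools)),
    stats::setNames(res, paste0("j_poc_res_", pools)),
    stats::setNames(min_, paste0("j_poc_min_", pools)),
    stats::setNames(bury, paste0("j_poc_bury_", pools)),
    j_c = min_[1] + min_[2]
  )
  new_state <- sediment_state(new_conc[1], new_conc[2], new_conc[3], state$ch4)
  list(state = new_state, fluxes = fl)
}

#' Temperature-dependent dissolved methane saturation
#'
#' `ch4_sat_ref * theta_sat^(20 - temp_c)`: saturation rises in colder water.
#'
#' @param temp_c Temperature (degC).
#' @param params A [diagenesis_params()].
#' @return Saturation concentration (gC m^-3).
#' @export
ch4_saturation <- function(temp_c, params = diagenesis_params()) {
  params$ch4_sat_ref * params$theta_sat^(20 - temp_c)
}

#' Partition diagenesis carbon between dissolved methane and bubbles
#'
#' Mineralized carbon net of the denitrification sink becomes methane. Up to
#' the dissolved-transport capacity it stays dissolved and is delivered to
#' the aerobic layer (`j_ch4_d`); production beyond the capacity escapes the
#' anaerobic layer directly as gas bubbles (`j_ch4_gas`). The two always sum
#' to `j_c - j_c_den`.
#'
#' @param j_c Carbon diagenesis flux (gC m^-2 day^-1).
#' @param j_c_den Carbon consumed by denitrification (gC m^-2 day^-1);
#'   cannot exceed `j_c`.
#' @param capacity Dissolved CH4 transport capacity (gC m^-2 day^-1),
#'   typically `v_diff * ch4_saturation(temp_c)`.
#' @return Named numeric vector `c(j_ch4_d, j_ch4_gas)`.
#' @export
#' @examples
#' methane_partition(0.35, 0.05, capacity = 0.10)
methane_partition <- function(j_c, j_c_den = 0, capacity = Inf) {
  if (j_c < 0 || j_c_den < 0 || capacity < 0) {
    stop("methane partition inputs must be nonnegative", call. = FALSE)
  }
  if (j_c_den > j_c) {
    stop("denitrification cannot consume more carbon than diagenesis supplies",
         call. = FALSE)
  }
  prod <- j_c - j_c_den
  d <- min(prod, capacity)
  c(j_ch4_d = d, j_ch4_gas = prod - d)
}

#' Advance the aerobic-layer methane balance one step
#'
#' Dissolved methane delivered from the anaerobic layer is lost by diffusion
#' to the overlying water (`v_diff * CH4`), oxidation to CO2
#' (`k_ch4_ox * theta_ch4_ox^(T-20) * CH4 * H1`) and resuspension. The layer
#' is 1 mm thin, so loss rates far exceed 1/day; the update is a backward
#' (implicit) Euler step, which is unconditionally stable, keeps the
#' concentration nonnegative, conserves mass exactly, and has the closed-form
#' steady state `CH4* = j_ch4_d / (v_diff + v_ox + v_res)` as its fixed point
#' at any step length.
#'
#' @param state A [sediment_state()] (only `ch4` is used and updated).
#' @param j_ch4_d Dissolved CH4 delivered from the anaerobic layer
#'   (gC m^-2 day^-1).
#' @param j_sed_r Resuspended bed-sediment mass flux (g m^-2 day^-1).
#' @param temp_c Temperature (degC).
#' @param params A [diagenesis_params()].
#' @param geom A [layer_geometry()].
#' @param dt Step length (day).
#' @return List with `state` (updated) and `fluxes`, a named vector of
#'   `j_ch4_w` (diffusion to water), `j_ch4_r` (resuspension) and `j_ch4_o`
#'   (oxidation), all gC m^-2 day^-1.
#' @export
step_aerobic_ch4 <- function(state, j_ch4_d, j_sed_r, temp_c,
                             params = diagenesis_params(),
                             geom = layer_geometry(), dt = 1) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (j_ch4_d < 0 || j_sed_r < 0) {
    stop("fluxes must be nonnegative", call. = FALSE)
  }
  h1 <- geom$h1
  v_ox <- params$k_ch4_ox * params$theta_ch4_ox^(temp_c - 20) * h1
  v_res <- j_sed_r / (params$rho_sed * 1e6)
  v_tot <- params$v_diff + v_ox + v_res

  ch4_new <- (state$ch4 + dt * j_ch4_d / h1) / (1 + dt * v_tot / h1)
  fl <- c(j_ch4_w = params$v_diff * ch4_new,
          j_ch4_r = v_res * ch4_new,
          j_ch4_o = v_ox * ch4_new)
  new_state <- state
  new_state$ch4 <- ch4_new
  list(state = new_state, fluxes = fl)
}

#' Inorganic carbon release from the sediment
#'
#' Total CH4 + CO2 leaving the bed for the water column: dissolved methane
#' diffusion, methane bubbles from the anaerobic layer, and the CO2 produced
#' by aerobic methane oxidation (lost as gas bubbles).
#'
#' @param fluxes Named vector or one-row data frame holding `j_ch4_w`,
#'   `j_ch4_gas` and `j_ch4_o` (gC m^-2 day^-1).
#' @return Inorganic carbon release (gC m^-2 day^-1).
#' @export
inorganic_release <- function(fluxes) {
  fluxes <- as.list(fluxes)
  as.numeric(fluxes$j_ch4_w) + as.numeric(fluxes$j_ch4_gas) +
    as.numeric(fluxes$j_ch4_o)
}

#' Run one full sediment diagenesis step
#'
#' Orchestrates a day of benthic carbon cycling: the settled flux is split
#' into G fractions, the anaerobic pools advance (resuspension,
#' mineralization, burial), mineralized carbon is partitioned between
#' dissolved methane and bubbles, and the aerobic methane layer advances
#' (diffusion, oxidation, resuspension). The effective denitrification sink
#' is `min(params$j_c_den, j_c)` — it cannot exceed supply.
#'
#' @param state A [sediment_state()].
#' @param j_settled Total organic carbon settling flux (gC m^-2 day^-1),
#'   including any algal debris.
#' @param j_sed_r Resuspended bed-sediment mass flux (g m^-2 day^-1).
#' @param temp_c Temperature (degC).
#' @param params A [diagenesis_params()].
#' @param geom A [layer_geometry()].
#' @param dt Step length (day).
#' @return List with `state` (updated [sediment_state()]) and `fluxes`, a
#'   named numeric vector with every interface flux: per-pool deposition,
#'   resuspension, mineralization and burial, `j_c`, `j_c_den`, `j_ch4_d`,
#'   `j_ch4_gas`, `j_ch4_w`, `j_ch4_r`, `j_ch4_o` (gC m^-2 day^-1).
#' @export
#' @examples
#' st <- sediment_state()
#' out <- diagenesis_step(st, j_settled = 1, j_sed_r = 0, temp_c = 20)
#' out$fluxes[["j_c"]]
diagenesis_step <- function(state, j_settled, j_sed_r, temp_c,
                            params = diagenesis_params(),
                            geom = layer_geometry(), dt = 1) {
  dep <- partition_deposition(j_settled, params)
  an <- step_anaerobic(state, dep, j_sed_r, temp_c, params, geom, dt)
  j_c <- an$fluxes[["j_c"]]
  j_den <- min(params$j_c_den, j_c)
  cap <- params$v_diff * ch4_saturation(temp_c, params)
  part <- methane_partition(j_c, j_den, cap)
  ae <- step_aerobic_ch4(an$state, part[["j_ch4_d"]], j_sed_r, temp_c,
                         params, geom, dt)
  list(
    state = ae$state,
    fluxes = c(an$fluxes, j_c_den = j_den, part, ae$fluxes)
  )
}
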