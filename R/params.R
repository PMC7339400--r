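#' Sediment layer geometry
#'
#' The bed is discretised into a thin aerobic surface layer over a thicker
#' anaerobic layer. Organic carbon settles into the anaerobic layer; dissolved
#' methane produced there is processed (oxidised, diffused, resuspended) in
#' the aerobic layer.
#'
#' @param h1 Aerobic-layer thickness (m). Default 0.001 (1 mm).
#' @param h2 Anaerobic-layer thickness (m). Default 0.1 (10 cm).
#' @return A `layer_geometry` list with elements `h1` and `h2`.
#' @export
#' @examples
#' layer_geometry()
layer_geometry <- function(h1 = 0.001, h2 = 0.1) {
  stopifnot(is.numeric(h1), is.numeric(h2), length(h1) == 1, length(h2) == 1)
  if (h1 <= 0 || h2 <= 0) {
    stop("layer thicknesses must be strictly positive", call. = FALSE)
  }
  structure(list(h1 = h1, h2 = h2), class = "layer_geometry")
}

#' Sediment diagenesis parameters
#'
#' Rates and coefficients of the two-layer benthic diagenesis model. Settled
#' organic carbon is split into a labile (G1), a slow-reacting (G2) and a
#' non-reacting (G3) fraction; G1 and G2 mineralize by first-order kinetics
#' with Arrhenius-style temperature correction, all pools are buried at a
#' constant burial velocity and resuspended in proportion to bed-sediment
#' resuspension. Mineralized carbon (less an optional denitrification sink)
#' becomes dissolved methane; production above a dissolved-transport capacity
#' escapes as bubbles.
#'
#' Defaults follow the standard water-quality-model parameterisation of the
#' three-G diagenesis framework: G fractions (0.65, 0.20, 0.15), mineralization
#' rates 0.035 and 0.0018 day^-1 with temperature bases 1.1 and 1.15, and a
#' burial velocity of 6.85e-6 m day^-1.
#'
#' @param f_g1,f_g2,f_g3 G-fraction split of settled organic carbon
#'   (unitless; must sum to 1).
#' @param k_g1,k_g2 First-order mineralization rates of the G1/G2 pools at
#'   20 degC (day^-1). `k_g1 > k_g2` is required (G1 is the labile pool).
#' @param theta_g1,theta_g2 Temperature-correction bases for mineralization.
#' @param w_bury Burial velocity (m day^-1).
#' @param rho_sed Bed sediment density (Mg m^-3).
#' @param ch4_sat_ref Dissolved CH4 saturation at 20 degC (gC m^-3).
#' @param theta_sat Temperature base of CH4 saturation (saturation increases
#'   as water cools: `sat(T) = ch4_sat_ref * theta_sat^(20 - T)`).
#' @param k_ch4_ox Aerobic CH4 oxidation rate (day^-1).
#' @param theta_ch4_ox Temperature base for CH4 oxidation.
#' @param v_diff CH4 sediment-water mass-transfer (diffusion) velocity
#'   (m day^-1).
#' @param j_c_den Carbon flux consumed by denitrification
#'   (gC m^-2 day^-1). Defaults to 0; nitrogen cycling is outside this model,
#'   but a known nitrate reduction flux can be expressed as carbon via the
#'   stoichiometric constant `C_PER_NO3N` (gC per gN).
#' @return A `diagenesis_params` list.
#' @seealso [step_anaerobic()], [step_aerobic_ch4()], [layer_geometry()]
#' @export
diagenesis_params <- function(f_g1 = 0.65, f_g2 = 0.20, f_g3 = 0.15,
                              k_g1 = 0.035, k_g2 = 0.0018,
                              theta_g1 = 1.1, theta_g2 = 1.15,
                              w_bury = 6.85e-6,
                              rho_sed = 1.6,
                              ch4_sat_ref = 37, theta_sat = 1.024,
                              k_ch4_ox = 100, theta_ch4_ox = 1.079,
                              v_diff = 0.5,
                              j_c_den = 0) {
  p <- list(
    f_g1 = f_g1, f_g2 = f_g2, f_g3 = f_g3,
    k_g1 = k_g1, k_g2 = k_g2,
    theta_g1 = theta_g1, theta_g2 = theta_g2,
    w_bury = w_bury, rho_sed = rho_sed,
    ch4_sat_ref = ch4_sat_ref, theta_sat = theta_sat,
    k_ch4_ox = k_ch4_ox, theta_ch4_ox = theta_ch4_ox,
    v_diff = v_diff, j_c_den = j_c_den
  )
  bad <- names(p)[!vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x), logical(1))]
  if (length(bad)) {
    stop("non-numeric diagenesis parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (abs(f_g1 + f_g2 + f_g3 - 1) > 1e-9) {
    stop("G fractions must sum to 1 (got ", f_g1 + f_g2 + f_g3, ")",
         call. = FALSE)
  }
  if (any(unlist(p) < 0)) {
    stop("diagenesis rates, fractions and velocities must be nonnegative",
         call. = FALSE)
  }
  if (k_g1 <= k_g2) {
    stop("k_g1 must exceed k_g2: G1 is the labile pool", call. = FALSE)
  }
  if (rho_sed <= 0) stop("rho_sed must be positive", call. = FALSE)
  structure(p, class = "diagenesis_params")
}

#' Stoichiometric carbon equivalent of denitrified nitrate (gC per gN)
#'
#' From 5 CH2O + 4 NO3- consuming 5 carbon per 4 nitrogen:
#' 5*12 / (4*14).
#' @export
C_PER_NO3N <- 5 * 12 / (4 * 14)

#' Oxygen equivalent of organic carbon (gO2 per gC)
#'
#' Conversion constant for reporting fluxes in oxygen units (e.g. sediment
#' oxygen demand); all internal computation stays in carbon units.
#' @export
O2_PER_C <- 2.67

#' Sediment state of the diagenesis model
#'
#' @param poc_g1,poc_g2,poc_g3 Organic carbon concentration of the labile,
#'   slow-reacting and non-reacting pools in the anaerobic layer (gC m^-3).
#' @param ch4 Dissolved methane concentration in the aerobic layer (gC m^-3).
#' @return A `sediment_state` list.
#' @export
sediment_state <- function(poc_g1 = 0, poc_g2 = 0, poc_g3 = 0, ch4 = 0) {
  x <- list(poc_g1 = poc_g1, poc_g2 = poc_g2, poc_g3 = poc_g3, ch4 = ch4)
  if (any(unlist(x) < 0)) {
    stop("sediment concentrations must be nonnegative", call. = FALSE)
  }
  structure(x, class = "sediment_state")
}

#' Reach routing parameters
#'
#' Parameters of the single well-mixed reach: settling velocities for labile
#' and refractory particulate organic carbon (LPOC/RPOC), the simplified
#' Bagnold stream-power sediment-transport coefficients (SPCON, SPEXP and the
#' peak-rate factor PRF), the POC enrichment ratio of eroded soil, and
#' first-order water-column transformation rates. Defaults are the calibrated
#' values for a small Mid-Atlantic coastal-plain watershed: `v_lpoc = 0.12`,
#' `v_rpoc = 0.36` m day^-1, `er_poc = 2.98`, `spcon = 0.003238`,
#' `spexp = 1.1975`, `prf = 0.022`.
#'
#' @param v_lpoc,v_rpoc Settling velocities of labile/refractory POC
#'   (m day^-1).
#' @param spcon Linear coefficient of the sediment transport capacity;
#'   carries the concentration unit (with the default calibration the
#'   capacity comes out in Mg m^-3, see [max_sediment_conc()]).
#' @param spexp Exponent of the sediment transport capacity.
#' @param prf Peak-rate adjustment factor applied to channel velocity.
#' @param er_poc POC enrichment ratio of eroded sediment (unitless).
#' @param k_doc_min Water-column DOC mineralization rate (day^-1).
#' @param k_poc_diss Water-column POC dissolution rate (day^-1), a source of
#'   in-river (autochthonous) DOC.
#' @param lpoc_frac Fraction of upland POC load entering the labile pool
#'   (remainder is refractory).
#' @param algal_doc Algal-mortality DOC source (kgC day^-1), default 0.
#' @return A `routing_params` list.
#' @export
routing_params <- function(v_lpoc = 0.12, v_rpoc = 0.36,
                           spcon = 0.003238, spexp = 1.1975, prf = 0.022,
                           er_poc = 2.98,
                           k_doc_min = 0.005, k_poc_diss = 0.002,
                           lpoc_frac = 0.5, algal_doc = 0) {
  p <- list(v_lpoc = v_lpoc, v_rpoc = v_rpoc, spcon = spcon, spexp = spexp,
            prf = prf, er_poc = er_poc, k_doc_min = k_doc_min,
            k_poc_diss = k_poc_diss, lpoc_frac = lpoc_frac,
            algal_doc = algal_doc)
  bad <- names(p)[!vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x), logical(1))]
  if (length(bad)) {
    stop("non-numeric routing parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(unlist(p) < 0)) {
    stop("routing parameters must be nonnegative", call. = FALSE)
  }
  if (lpoc_frac > 1) stop("lpoc_frac must lie in [0, 1]", call. = FALSE)
  structure(p, class = "routing_params")
}

#' Reach geometry
#'
#' Fixed plan geometry of the modeled reach; depth and velocity vary daily and
#' are part of the forcing.
#'
#' @param length Reach length (m).
#' @param width Reach (and bed) width (m).
#' @return A `reach_geometry` list with `length`, `width` and derived bed
#'   area `area` (m^2).
#' @export
reach_geometry <- function(length = 20000, width = 30) {
  stopifnot(is.numeric(length), is.numeric(width))
  if (length <= 0 || width <= 0) {
    stop("reach length and width must be positive", call. = FALSE)
  }
  structure(list(length = length, width = width, area = length * width),
            class = "reach_geometry")
}

#' Water column state of the reach
#'
#' @param lpoc,rpoc Labile/refractory particulate organic carbon (gC m^-3).
#' @param doc_alloch,doc_autoch Dissolved organic carbon by source tag,
#'   terrestrial (allochthonous) vs in-river (autochthonous) (gC m^-3).
#' @param sed Suspended sediment (g m^-3).
#' @return A `water_column_state` list.
#' @export
water_column_state <- function(lpoc = 0, rpoc = 0, doc_alloch = 0,
                               doc_autoch = 0, sed = 0) {
  x <- list(lpoc = lpoc, rpoc = rpoc, doc_alloch = doc_alloch,
            doc_autoch = doc_autoch, sed = sed)
  if (any(unlist(x) < 0)) {
    stop("water column concentrations must be nonnegative", call. = FALSE)
  }
  structure(x, class = "water_column_state")
}
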