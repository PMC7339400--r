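# Small deterministic fixtures shared across test files.

# constant forcing: handy for steady-state checks
constant_forcing <- function(n, flow = 2, depth = 0.6, velocity = 0.4,
                             temp = 20, sed_yield = 0, poc_load = 0,
                             doc_load = 0, algal_debris = 0,
                             start = "2014-01-01") {
  tibble::tibble(
    date = as.Date(start) + seq_len(n) - 1,
    flow = flow, velocity = velocity, depth = depth, temp = temp,
    sed_yield = sed_yield, poc_load = poc_load, doc_load = doc_load,
    algal_debris = algal_debris
  )
}

# random nonnegative forcing for property tests
random_forcing <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    date = as.Date("2014-01-01") + seq_len(n) - 1,
    flow = 0.5 + rexp(n, 1 / 2),
    velocity = runif(n, 0.1, 0.8),
    depth = runif(n, 0.3, 1.2),
    temp = runif(n, 2, 28),
    sed_yield = rexp(n, 1 / 40),
    poc_load = rexp(n, 1 / 2000),
    doc_load = rexp(n, 1 / 2500),
    algal_debris = rbinom(n, 1, 0.2) * runif(n, 0, 0.05)
  )
}

# paper-style annual budget table used for the worked-arithmetic checks
printed_budget <- function() {
  tibble::tibble(
    constituent = c("POC", "DOC"),
    watershed_contribution = c(36.6, 46),
    riverine_contribution = c(0.05, 0.72),
    outlet_outflow = c(24.5, 46.3),
    deposition = c(11.44, NA),
    resuspension = c(0.04, NA),
    burial = c(0.34, NA)
  )
}
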