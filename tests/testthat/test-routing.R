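test_that("upland POC load scales sediment by carbon content and enrichment", {
  expect_equal(upland_poc_load(0, 0.01, 2.98), 0)
  expect_equal(upland_poc_load(1, 0.01, 2.98), 29.8)
  expect_equal(upland_poc_load(3, 1, 1), 3000)
  expect_error(upland_poc_load(-1, 0.01, 1), "nonnegative")
})

test_that("sediment transport capacity follows the stream-power form", {
  p <- routing_params()
  expect_equal(max_sediment_conc(0, p), 0)
  p1 <- routing_params(spcon = 1, spexp = 1, prf = 1)
  expect_equal(max_sediment_conc(2, p1), 2)
  # oracle: direct power computation at the calibrated values
  expect_equal(max_sediment_conc(1, p), 0.003238 * 0.022^1.1975)
  expect_error(max_sediment_conc(-1, p), "nonnegative")
})

test_that("sediment exchange settles excess, resuspends deficit, conserves mass", {
  eq <- sediment_exchange(4, 4, 100, 1)
  expect_equal(eq$deposition, 0)
  expect_equal(eq$j_sed_r, 0)

  dep <- sediment_exchange(10, 4, 0, 1)
  expect_equal(dep$deposition, 6)
  expect_equal(dep$sed_conc, 4)
  expect_equal(dep$bed_store, 6)

  res <- sediment_exchange(1, 6, 1, 1)
  expect_equal(res$j_sed_r, 1)
  expect_equal(res$bed_store, 0)
  expect_equal(res$sed_conc, 2)

  set.seed(9)
  for (i in 1:50) {
    conc <- rexp(1, 1 / 20); cmx <- rexp(1, 1 / 20)
    store <- rexp(1, 1 / 50); depth <- runif(1, 0.2, 2)
    out <- sediment_exchange(conc, cmx, store, depth)
    before <- conc * depth + store
    after <- out$sed_conc * depth + out$bed_store
    expect_equal(after, before, tolerance = 1e-9)
    expect_true(out$deposition == 0 || out$j_sed_r == 0)
  }
})

test_that("POC settling flux is linear in concentration and velocity", {
  expect_equal(poc_settling_flux(0, 0.12), 0)
  expect_equal(poc_settling_flux(1, 0.12), 0.12)
  expect_equal(poc_settling_flux(2, 0.36), 0.72)
})

test_that("reach with zero state and loads stays at zero", {
  out <- step_reach(water_column_state(), constant_forcing(1)[1, ])
  expect_equal(sum(out$outlet), 0)
  expect_equal(sum(unlist(out$state)), 0)
  expect_equal(out$j_sed_r, 0)
})

test_that("conservative tracer passes the upland load through at steady state", {
  p <- routing_params(v_lpoc = 0, v_rpoc = 0, k_doc_min = 0, k_poc_diss = 0)
  wc <- water_column_state()
  day <- constant_forcing(1, poc_load = 1000, doc_load = 800)[1, ]
  for (i in 1:300) {
    out <- step_reach(wc, day, p)
    wc <- out$state
  }
  expect_equal(out$outlet[["lpoc"]] + out$outlet[["rpoc"]], 1000,
               tolerance = 1e-9)
  expect_equal(out$outlet[["doc_alloch"]], 800, tolerance = 1e-9)
})

test_that("settling-only steady state matches the CSTR closed form", {
  p <- routing_params(k_doc_min = 0, k_poc_diss = 0, lpoc_frac = 0.5)
  g <- reach_geometry()
  day <- constant_forcing(1, flow = 2, depth = 0.6, poc_load = 1000)[1, ]
  wc <- water_column_state()
  for (i in 1:400) {
    out <- step_reach(wc, day, p, g)
    wc <- out$state
  }
  q <- 2 * 86400
  expect_equal(out$outlet[["lpoc"]],
               500 / (1 + p$v_lpoc * g$area / q), tolerance = 1e-9)
  expect_equal(out$outlet[["rpoc"]],
               500 / (1 + p$v_rpoc * g$area / q), tolerance = 1e-9)
})

test_that("allochthonous DOC never migrates to the autochthonous tag", {
  p <- routing_params(k_poc_diss = 0.01)
  wc <- water_column_state()
  day <- constant_forcing(1, doc_load = 500, poc_load = 0)[1, ]
  for (i in 1:50) {
    out <- step_reach(wc, day, p)
    wc <- out$state
  }
  expect_equal(wc$doc_autoch, 0)
  expect_equal(out$outlet[["doc_autoch"]], 0)
  # and dissolution feeds only the autochthonous tag
  day2 <- constant_forcing(1, doc_load = 0, poc_load = 500)[1, ]
  wc <- water_column_state()
  for (i in 1:50) {
    out <- step_reach(wc, day2, p)
    wc <- out$state
  }
  expect_gt(wc$doc_autoch, 0)
  expect_equal(wc$doc_alloch, 0)
})

test_that("raising the LPOC settling velocity shifts carbon from outlet to bed", {
  f <- random_forcing(180, seed = 31)
  outs <- deps <- numeric(0)
  for (v in c(0.06, 0.12, 0.24, 0.48)) {
    sim <- run_simulation(f, rparams = routing_params(v_lpoc = v))
    outs <- c(outs, sum(sim$daily$out_lpoc + sim$daily$out_rpoc))
    deps <- c(deps, sum(sim$daily$dep_poc_kg))
  }
  expect_true(all(diff(outs) < 0))
  expect_true(all(diff(deps) > 0))
})

test_that("zero SPCON shuts resuspension off for the whole run", {
  f <- random_forcing(200, seed = 12)
  sim <- run_simulation(f, rparams = routing_params(spcon = 0))
  expect_true(all(sim$daily$j_sed_r == 0))
  expect_true(all(sim$daily$res_poc_kg == 0))
})

test_that("step_reach rejects incomplete forcing", {
  day <- constant_forcing(1)[1, ]
  day$flow <- NULL
  expect_error(step_reach(water_column_state(), day), "missing")
})
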