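test_that("deposition partitions over the G pools and sums to the input", {
  p <- diagenesis_params()
  expect_equal(unname(partition_deposition(0, p)), c(0, 0, 0))
  expect_equal(unname(partition_deposition(1, p)), c(0.65, 0.20, 0.15))

  p1 <- diagenesis_params(f_g1 = 1, f_g2 = 0, f_g3 = 0)
  expect_equal(unname(partition_deposition(2.5, p1)), c(2.5, 0, 0))

  set.seed(11)
  for (j in rexp(20, 1 / 5)) {
    expect_equal(sum(partition_deposition(j, p)), j)
  }
  expect_error(partition_deposition(-1, p), "negative")
})

test_that("resuspension flux follows the porewater form and the mass limiter", {
  expect_equal(poc_resuspension_flux(0, 1, 1000), 0)
  expect_equal(poc_resuspension_flux(1000, 1.0, 1000), 1.0)
  expect_equal(
    poc_resuspension_flux(1000, 1.0, 1e9, available_mass = 100, dt = 1), 100)
  expect_equal(ch4_resuspension_flux(0, 1, 1e5), 0)
  expect_equal(ch4_resuspension_flux(10, 1.0, 1e5), 1.0)
  expect_equal(ch4_resuspension_flux(10, 1.0, 1e12, available_mass = 2), 2)
  expect_error(poc_resuspension_flux(10, 0, 10), "rho_sed")
})

test_that("mineralization flux is first-order with temperature correction; G3 inert", {
  expect_equal(poc_mineralization_flux(0, 0.035, 1.1, 20, 0.1), 0)
  expect_equal(poc_mineralization_flux(100, 0.035, 1.1, 20, 0.1), 0.35)
  # 10 degC warmer multiplies by theta^10
  expect_equal(poc_mineralization_flux(100, 0.035, 1.1, 30, 0.1),
               0.35 * 1.1^10)
  expect_equal(poc_mineralization_flux(500, 0.035, 1.1, 25, 0.1, pool = "g3"),
               0)
})

test_that("burial flux is velocity times concentration", {
  expect_equal(poc_burial_flux(0, 6.85e-6), 0)
  expect_equal(poc_burial_flux(1000, 6.85e-6), 6.85e-3)
  expect_equal(poc_burial_flux(1234, 0), 0)
})

test_that("anaerobic pools reach the closed-form steady state", {
  p <- diagenesis_params()
  st <- sediment_state()
  dep <- c(g1 = 0.1, g2 = 0, g3 = 0)
  for (i in 1:4000) {
    st <- step_anaerobic(st, dep, 0, 20, p)$state
  }
  expect_equal(st$poc_g1, 0.1 / (0.035 * 0.1 + 6.85e-6), tolerance = 1e-3)
  # 1-day Euler fixed point equals the continuous steady state; a finer step
  # must converge to the same value
  st2 <- sediment_state()
  for (i in 1:40000) {
    st2 <- step_anaerobic(st2, dep, 0, 20, p, dt = 0.1)$state
  }
  expect_equal(st2$poc_g1, st$poc_g1, tolerance = 1e-2)
})

test_that("G3 accumulates deposition exactly when burial and resuspension are off", {
  p <- diagenesis_params(w_bury = 0)
  st <- sediment_state()
  dep <- c(g1 = 0, g2 = 0, g3 = 0.15)
  for (i in 1:10) st <- step_anaerobic(st, dep, 0, 20, p)$state
  expect_equal(st$poc_g3, 0.15 * 10 / 0.1)
  expect_equal(st$poc_g1, 0)
})

test_that("each pool conserves carbon step by step under random forcing", {
  p <- diagenesis_params()
  g <- layer_geometry()
  set.seed(7)
  st <- sediment_state(poc_g1 = 50, poc_g2 = 80, poc_g3 = 40)
  for (i in 1:200) {
    dep <- partition_deposition(rexp(1, 1 / 0.5), p)
    jr <- rbinom(1, 1, 0.3) * rexp(1, 1 / 5000)
    temp <- runif(1, 0, 30)
    out <- step_anaerobic(st, dep, jr, temp, p, g)
    f <- out$fluxes
    for (k in 1:3) {
      pool <- c("g1", "g2", "g3")[k]
      lhs <- dep[[k]]
      rhs <- (out$state[[paste0("poc_", pool)]] - st[[paste0("poc_", pool)]]) *
        g$h2 +
        f[[paste0("j_poc_res_", pool)]] + f[[paste0("j_poc_min_", pool)]] +
        f[[paste0("j_poc_bury_", pool)]]
      expect_equal(rhs, lhs, tolerance = 1e-9)
    }
    st <- out$state
  }
})

test_that("methane partition preserves the production identity", {
  expect_equal(unname(methane_partition(0, 0, 1)), c(0, 0))
  expect_equal(unname(methane_partition(0.35, 0, 1.0)), c(0.35, 0))
  expect_equal(unname(methane_partition(0.35, 0.05, 0.10)), c(0.10, 0.20))
  set.seed(3)
  for (i in 1:20) {
    jc <- rexp(1); den <- runif(1, 0, jc); cap <- rexp(1, 2)
    out <- methane_partition(jc, den, cap)
    expect_equal(sum(out), jc - den)
    expect_true(all(out >= 0))
  }
  expect_error(methane_partition(0.1, 0.2, 1), "denitrification")
})

test_that("aerobic methane layer conserves mass and matches steady-state ratios", {
  p <- diagenesis_params()
  g <- layer_geometry()
  st <- sediment_state()
  out <- step_aerobic_ch4(st, 0, 0, 20, p, g)
  expect_equal(unname(out$fluxes), c(0, 0, 0))
  expect_equal(out$state$ch4, 0)

  # single-sink steady state: everything delivered diffuses out
  p0 <- diagenesis_params(k_ch4_ox = 0)
  st <- sediment_state()
  for (i in 1:50) {
    r <- step_aerobic_ch4(st, 0.4, 0, 20, p0, g)
    st <- r$state
  }
  expect_equal(r$fluxes[["j_ch4_w"]], 0.4, tolerance = 1e-6)
  expect_equal(r$fluxes[["j_ch4_o"]], 0)

  # oxidation on: diffusion/oxidation ratio equals the rate ratio at any step
  st <- sediment_state(ch4 = 5)
  for (temp in c(5, 20, 27)) {
    r <- step_aerobic_ch4(st, 0.2, 0, temp, p, g)
    v_ox <- p$k_ch4_ox * p$theta_ch4_ox^(temp - 20) * g$h1
    expect_equal(r$fluxes[["j_ch4_w"]] / r$fluxes[["j_ch4_o"]],
                 p$v_diff / v_ox)
    # conservation of the step
    lhs <- 0.2
    rhs <- (r$state$ch4 - st$ch4) * g$h1 + sum(r$fluxes)
    expect_equal(rhs, lhs, tolerance = 1e-9)
  }
})

test_that("inorganic release sums the methane-derived pathways", {
  expect_equal(inorganic_release(c(j_ch4_w = 0, j_ch4_gas = 0, j_ch4_o = 0)), 0)
  expect_equal(
    inorganic_release(c(j_ch4_w = 0.1, j_ch4_gas = 0.2, j_ch4_o = 0.05)), 0.35)

  # combined identity: release = j_c - den - resusp - CH4 storage change
  p <- diagenesis_params()
  g <- layer_geometry()
  st <- sediment_state(poc_g1 = 300, poc_g2 = 200, poc_g3 = 100, ch4 = 2)
  out <- diagenesis_step(st, 1.2, 4000, 18, p, g)
  f <- out$fluxes
  expect_equal(
    inorganic_release(f),
    f[["j_c"]] - f[["j_c_den"]] - f[["j_ch4_r"]] -
      (out$state$ch4 - st$ch4) * g$h1,
    tolerance = 1e-9
  )
})

test_that("whole-sediment carbon is conserved every step under random forcing", {
  p <- diagenesis_params(j_c_den = 0.002)
  g <- layer_geometry()
  set.seed(21)
  st <- sediment_state(poc_g1 = 20, poc_g2 = 30, poc_g3 = 10, ch4 = 1)
  for (i in 1:300) {
    dep <- rexp(1, 1 / 0.8)
    jr <- rbinom(1, 1, 0.25) * rexp(1, 1 / 8000)
    temp <- runif(1, 0, 30)
    out <- diagenesis_step(st, dep, jr, temp, p, g)
    f <- out$fluxes
    storage0 <- (st$poc_g1 + st$poc_g2 + st$poc_g3) * g$h2 + st$ch4 * g$h1
    storage1 <- (out$state$poc_g1 + out$state$poc_g2 + out$state$poc_g3) *
      g$h2 + out$state$ch4 * g$h1
    res <- f[["j_poc_res_g1"]] + f[["j_poc_res_g2"]] + f[["j_poc_res_g3"]] +
      f[["j_ch4_r"]]
    bury <- f[["j_poc_bury_g1"]] + f[["j_poc_bury_g2"]] + f[["j_poc_bury_g3"]]
    closure <- storage1 - storage0 + res + bury + inorganic_release(f) +
      f[["j_c_den"]]
    expect_equal(closure, dep, tolerance = 1e-9)
    # nonnegativity of everything
    expect_true(all(f >= 0))
    expect_true(all(unlist(out$state) >= 0))
    st <- out$state
  }
})

test_that("zero sediment resuspension reduces to the pure diagenesis model", {
  p <- diagenesis_params()
  set.seed(5)
  st <- sediment_state(poc_g1 = 100, poc_g2 = 50, poc_g3 = 25, ch4 = 3)
  for (i in 1:50) {
    out <- diagenesis_step(st, rexp(1), 0, runif(1, 5, 25), p)
    f <- out$fluxes
    expect_identical(unname(f[c("j_poc_res_g1", "j_poc_res_g2",
                                "j_poc_res_g3", "j_ch4_r")]),
                     c(0, 0, 0, 0))
    st <- out$state
  }
})

test_that("parameter constructors enforce their invariants", {
  expect_error(diagenesis_params(f_g1 = 0.5, f_g2 = 0.5, f_g3 = 0.5), "sum")
  expect_error(diagenesis_params(k_g1 = 0.001, k_g2 = 0.01), "labile")
  expect_error(diagenesis_params(w_bury = -1), "nonnegative")
  expect_error(layer_geometry(h1 = 0), "positive")
  expect_error(sediment_state(poc_g1 = -1), "nonnegative")
  expect_error(step_anaerobic(sediment_state(), c(g1 = 0, g2 = 0, g3 = 0),
                              0, 20, dt = 0), "dt")
  expect_error(step_aerobic_ch4(sediment_state(), 0.1, 0, 20, dt = -1), "dt")
})
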