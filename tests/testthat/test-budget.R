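# daily table with the columns annual_budget() consumes
budget_daily <- function(dates, poc_in = 0, doc_in = 0, out_poc = 0,
                         out_doc = 0, dep = 0, res = 0, bury = 0,
                         inorg = 0) {
  n <- length(dates)
  tibble::tibble(
    date = dates,
    poc_in_kg = rep_len(poc_in, n), doc_in_kg = rep_len(doc_in, n),
    algal_dep_kg = 0, algal_doc_kg = 0,
    out_lpoc = rep_len(out_poc, n) / 2, out_rpoc = rep_len(out_poc, n) / 2,
    out_doc_alloch = rep_len(out_doc, n), out_doc_autoch = 0,
    dep_poc_kg = rep_len(dep, n), res_poc_kg = rep_len(res, n),
    bury_kg = rep_len(bury, n), inorg_kg = rep_len(inorg, n),
    den_kg = 0, doc_diss_kg = 0
  )
}

test_that("annual accumulation averages complete calendar years", {
  d2014 <- seq(as.Date("2014-01-01"), as.Date("2014-12-31"), by = "day")
  b <- annual_budget(budget_daily(d2014, poc_in = 10), area_ha = 10)
  expect_equal(b$watershed_contribution[b$constituent == "POC"],
               365 * 10 / 10)

  # all-zero series gives an all-zero budget
  b0 <- annual_budget(budget_daily(d2014), area_ha = 10)
  expect_equal(b0$watershed_contribution, c(0, 0))
  expect_equal(b0$deposition[1], 0)

  # two years with different loads average
  d2 <- seq(as.Date("2014-01-01"), as.Date("2015-12-31"), by = "day")
  loads <- ifelse(format(d2, "%Y") == "2014", 100 / 365, 300 / 365)
  b2 <- annual_budget(budget_daily(d2, poc_in = loads), area_ha = 1)
  expect_equal(b2$watershed_contribution[1], 200, tolerance = 1e-12)

  # a trailing partial year is excluded by default but counted with "all"
  d3 <- seq(as.Date("2014-01-01"), as.Date("2015-03-31"), by = "day")
  b3 <- annual_budget(budget_daily(d3, poc_in = 1), area_ha = 1)
  expect_equal(b3$watershed_contribution[1], 365)
  b3all <- annual_budget(budget_daily(d3, poc_in = 1), area_ha = 1,
                         years = "all")
  expect_equal(b3all$watershed_contribution[1], length(d3) / (length(d3) / 365.25))

  expect_error(annual_budget(budget_daily(d2014), area_ha = 0), "area")
})

test_that("ratio table computes the budget quotients and handles zeros", {
  r <- ratio_table(printed_budget())
  poc <- r[r$constituent == "POC", ]
  expect_equal(poc$out_over_wc, 24.5 / 36.6)
  expect_equal(poc$res_over_dep, 0.04 / 11.44)
  expect_equal(poc$bury_over_ndep, 0.34 / (11.44 - 0.04))
  doc <- r[r$constituent == "DOC", ]
  expect_equal(doc$out_over_wc, 46.3 / 46)
  expect_true(is.na(doc$res_over_dep))

  zero <- tibble::tibble(watershed_contribution = 0, outlet_outflow = 5,
                         deposition = 0, resuspension = 0, burial = 1)
  rz <- ratio_table(zero)
  expect_true(is.na(rz$out_over_wc))
  expect_true(is.na(rz$res_over_dep))

  # reporting precision is opt-in
  expect_equal(ratio_table(printed_budget(), digits = 2)$out_over_wc[1], 0.67)
})

test_that("budget ratios are invariant under watershed-area rescaling", {
  d <- seq(as.Date("2014-01-01"), as.Date("2014-12-31"), by = "day")
  daily <- budget_daily(d, poc_in = 20, out_poc = 12, dep = 6, res = 0.1,
                        bury = 0.2, inorg = 4)
  r1 <- ratio_table(annual_budget(daily, area_ha = 100))
  r2 <- ratio_table(annual_budget(daily, area_ha = 5000))
  expect_equal(r1[-1], r2[-1])
})

test_that("benthic budget percentages are quotients of deposition and sum to 100", {
  eq <- benthic_budget(tibble::tibble(deposition = 10, resuspension = 2.5,
                                      burial = 2.5, inorganic_release = 2.5))
  expect_equal(eq$pct_resuspension, 25)
  expect_equal(eq$pct_accumulated, 25)

  set.seed(4)
  for (i in 1:20) {
    dep <- rexp(1, 1 / 10)
    parts <- runif(3, 0, dep / 3)
    bb <- benthic_budget(tibble::tibble(
      deposition = dep, resuspension = parts[1], burial = parts[2],
      inorganic_release = parts[3]))
    expect_equal(bb$pct_resuspension + bb$pct_burial + bb$pct_inorganic +
                   bb$pct_accumulated, 100, tolerance = 1e-9)
  }

  none <- benthic_budget(tibble::tibble(deposition = 0, resuspension = 0,
                                        burial = 0, inorganic_release = 0))
  expect_true(is.na(none$pct_inorganic))
  expect_error(benthic_budget(tibble::tibble(deposition = 1)), "missing")
})
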