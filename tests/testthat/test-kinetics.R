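test_that("respiratory quotient reproduces the printed table values", {
  expect_equal(respiratory_quotient(4.47, 4.56), 0.98)
  expect_equal(respiratory_quotient(9.52, 10.02), 0.95)
  for (x in c(0.3, 1, 12.7)) expect_equal(respiratory_quotient(x, x), 1)
  expect_error(respiratory_quotient(1, 0), "> 0")
})

test_that("carbon balance reproduces the printed recoveries", {
  bL <- carbon_balance(glucose = 33.96, biomass = 1.43, cer = 4.47,
                       riboflavin = 1.70, byproducts = 26.01)
  # the batch-L components are printed to 2 decimals and reproduce the
  # reported 98.94 only to within their rounding (exact arithmetic on the
  # printed rates gives 98.97)
  expect_equal(bL$recovery, 98.94, tolerance = 5e-4)
  bH <- carbon_balance(glucose = 31.92, biomass = 3.77, cer = 9.52,
                       riboflavin = 2.38, byproducts = 15.79)
  expect_equal(bH$recovery, 98.56)
  closed <- carbon_balance(glucose = 30, biomass = 10, cer = 10,
                           riboflavin = 5, byproducts = 5)
  expect_equal(closed$recovery, 100)
})

test_that("carbon balance input validation", {
  expect_error(carbon_balance(glucose = 10, biomass = NA_real_, cer = 1,
                              riboflavin = 1, byproducts = 1), "biomass")
  expect_error(carbon_balance(glucose = 0, biomass = 1, cer = 1,
                              riboflavin = 1, byproducts = 1), "> 0")
})

test_that("recovery is invariant to rescaling all carbon rates", {
  b1 <- carbon_balance(glucose = 33.96, biomass = 1.43, cer = 4.47,
                       riboflavin = 1.70, byproducts = 26.01)
  c <- 3.7
  b2 <- carbon_balance(glucose = 33.96 * c, biomass = 1.43 * c,
                       cer = 4.47 * c, riboflavin = 1.70 * c,
                       byproducts = 26.01 * c)
  expect_equal(b1$recovery, b2$recovery)
})

test_that("mass rates convert to carbon rates with the right formulas", {
  expect_equal(carbon_rate_from_mass_rate(5.66, "glucose"), 33.96)
  expect_equal(carbon_rate_from_mass_rate(5.32, "glucose"), 31.92)
  expect_equal(carbon_rate_from_mass_rate(0, "glucose"), 0)
  # g/gDCW/h route: glucose 1 g = 1000/180.16 mmol, 6 C each
  expect_equal(carbon_rate_from_mass_rate(1, "glucose", unit = "g"),
               1000 / 180.16 * 6)
  expect_equal(carbon_rate_from_mass_rate(0.1, "riboflavin", unit = "g"),
               0.1 / 376.36 * 1000 * 17)
  expect_error(carbon_rate_from_mass_rate(1, "unobtainium"), "unknown")
  expect_equal(carbon_rate_from_mass_rate(2, mw = 100, carbons = 4), 8)
})

test_that("specific rates recover generator parameters exactly without noise", {
  sc <- scenario_config("H", seed = 1)      # mu 0.092, Yxs 0.096
  tc <- generate_timecourse(sc)
  rt <- specific_rates(tc)
  expect_equal(rt$mu, 0.092, tolerance = 1e-6)
  expect_equal(rt$Yxs, 0.096, tolerance = 1e-6)
  expect_equal(rt$qRib, sc$qRib, tolerance = 1e-6)
  expect_equal(rt$qGlc, 0.092 / 0.096 / 180.16 * 1000, tolerance = 1e-8)
  expect_equal(rt$RQ, 0.95)
})

test_that("constant biomass gives zero growth rate", {
  tc <- data.frame(time = seq(0, 40, 4), DCW = 2,
                   glucose = seq(40, 20, length.out = 11))
  rt <- specific_rates(tc, window = c(0, 40))
  expect_equal(rt$mu, 0, tolerance = 1e-12)
})

test_that("median recovered growth rate is within 5% under 2% noise", {
  mus <- vapply(1:100, function(s) {
    tc <- generate_timecourse(scenario_config("H", seed = s,
                                              tc_noise_sd = 0.02))
    specific_rates(tc)$mu
  }, numeric(1))
  expect_lt(abs(stats::median(mus) - 0.092) / 0.092, 0.05)
})

test_that("degenerate time-course inputs are rejected", {
  tc <- generate_timecourse(scenario_config("H", seed = 1))
  expect_error(specific_rates(tc, window = c(40, 41)), "3 points")
  tc_bad <- tc; tc_bad$DCW[5] <- 0
  expect_error(specific_rates(tc_bad, window = c(0, 44)), "non-positive")
})

test_that("pool comparison flags separations and not identical groups", {
  same <- pool_compare(matrix(c(1, 1.1, 0.9), ncol = 1,
                              dimnames = list(NULL, "OAA")),
                       matrix(c(1, 1.05, 0.95), ncol = 1,
                              dimnames = list(NULL, "OAA")))
  expect_false(same$significant)
  far <- pool_compare(c(1, 1, 1.0001), c(10, 10.1, 9.9))
  expect_true(far$significant)
  expect_equal(far$direction, 1)
  # degenerate equal-constant groups: P = 1, no flag
  flat <- pool_compare(c(2, 2), c(2, 2))
  expect_equal(flat$p_value, 1)
})

test_that("pool_compare matches an independent Welch t-test implementation", {
  # hand-rolled Welch statistic as the reference
  welch_p <- function(a, b) {
    va <- stats::var(a) / length(a); vb <- stats::var(b) / length(b)
    t <- (mean(a) - mean(b)) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
    2 * stats::pt(-abs(t), df)
  }
  set.seed(42)
  n <- 3; d <- 3; reps <- 1000
  hits_pkg <- hits_ref <- logical(reps)
  for (i in seq_len(reps)) {
    a <- stats::rnorm(n, 0, 1); b <- stats::rnorm(n, d, 1)
    hits_pkg[i] <- pool_compare(a, b)$significant
    hits_ref[i] <- welch_p(a, b) < 0.05
  }
  expect_lt(abs(mean(hits_pkg) - mean(hits_ref)), 0.01)
  expect_identical(hits_pkg, hits_ref)
})

test_that("rates and time-course files round trip", {
  rates <- list(qGlc = 5.32, mu = 0.092, qRib = 0.054)
  p1 <- tempfile(fileext = ".yaml")
  write_rates(rates, p1)
  expect_equal(read_rates(p1), rates)
  tc <- generate_timecourse(scenario_config("L", seed = 3))
  p2 <- tempfile(fileext = ".csv")
  write_timecourse(tc, p2)
  tc2 <- read_timecourse(p2)
  expect_equal(tc2$DCW, tc$DCW, tolerance = 1e-10)
  expect_equal(tc2$glucose, tc$glucose, tolerance = 1e-10)
})
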