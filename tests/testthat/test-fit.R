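mix_fit <- tracer_mixture()

noiseless_measurements <- function(net, fm, sc, sd = 0.004) {
  frg <- default_fragments()
  clean <- simulate_fragments(net, fm, mix_fit, frg$emu)
  rows <- do.call(rbind, lapply(seq_len(nrow(frg)), function(i)
    data.frame(fragment = frg$fragment[i], emu = frg$emu[i],
               replicate = 1L,
               mass = seq_along(clean[[frg$emu[i]]]) - 1L,
               value = clean[[frg$emu[i]]], sd = sd,
               stringsAsFactors = FALSE)))
  rates <- data.frame(
    quantity = c("qGlc", "mu", "qRib", "co2_ex", "ldh", "ack"),
    value = c(sc$qGlc, sc$mu, sc$qRib, fm$net[["co2_ex"]],
              fm$net[["ldh"]], fm$net[["ack"]]),
    sd = 0.005 * c(sc$qGlc, sc$mu, sc$qRib, fm$net[["co2_ex"]],
                   fm$net[["ldh"]], fm$net[["ack"]]))
  measurement_set(rows, rates)
}

test_that("noiseless synthetic data is refit to machine-level SSR and
           recovers the identifiable fluxes", {
  net <- build_default_network()
  sc <- scenario_config("H", seed = 7)
  fm <- generate_flux_map(net, sc)
  ms <- noiseless_measurements(net, fm, sc)
  fit <- suppressWarnings(
    fit_fluxes(net, ms, mix_fit,
               fit_config(restarts = 6, seed = 11, stop_ssr = 1e-8)))
  expect_lt(fit$ssr, 1e-6)
  major <- abs(fm$net) > 1e-3 * fm$net[["upt"]]
  rel_err <- abs(fit$fluxes$net[major] - fm$net[major]) /
    abs(fm$net[major])
  expect_lt(max(rel_err), 1e-3)
  expect_true(fit$chi2_pass)
  expect_gte(fit$n_restarts_converged, 1)
})

test_that("chi-square acceptance threshold matches an independent quantile
           computation and is monotone at the boundary", {
  # independent quantile: root of the distribution function
  q_oracle <- function(p, df)
    stats::uniroot(function(x) stats::pchisq(x, df) - p,
                   c(1e-8, 1e4), tol = 1e-10)$root
  for (df in c(1, 10, 32)) {
    thr <- chi2_accept(1, df)$threshold
    expect_equal(thr, q_oracle(0.95, df), tolerance = 1e-6)
  }
  thr10 <- chi2_accept(0, 10)$threshold
  expect_true(chi2_accept(0, 10)$pass)
  expect_true(chi2_accept(thr10 - 1e-9, 10)$pass)
  expect_false(chi2_accept(thr10 + 1e-9, 10)$pass)
  expect_error(chi2_accept(1, 0), "dof")
  expect_error(chi2_accept(-1, 5), "ssr")
})

test_that("flux normalization maps uptake to 100%", {
  net <- build_default_network()
  fm <- generate_flux_map(net, scenario_config("H", seed = 1))
  nrm <- normalize_to_uptake(fm, fm$net[["upt"]])
  expect_equal(unname(nrm["upt"]), 100)
  fm2 <- fm; fm2$net[["pgi"]] <- 2.66
  expect_equal(unname(normalize_to_uptake(fm2, 5.32)["pgi"]), 50)
  expect_error(normalize_to_uptake(fm, 0), "positive")
  expect_error(normalize_to_uptake(fm, -2), "positive")
})

test_that("measurement sets validate their inputs", {
  expect_error(measurement_set(data.frame(a = 1)), "columns")
  good <- data.frame(fragment = "X", emu = "Pyr|1,2,3", replicate = 1,
                     mass = 0:3, value = c(0.4, 0.3, 0.2, 0.1), sd = 0.004)
  expect_s3_class(measurement_set(good), "measurement_set")
  bad <- good; bad$sd <- 0
  expect_error(measurement_set(bad), "> 0")
  expect_error(
    measurement_set(good, data.frame(quantity = "qGlc", value = 5,
                                     sd = -1)), "> 0")
})

toy_measurements <- function(net, fm, frag, noise_sd, seed, rate_rxn,
                             rate_sd_rel = 0.01) {
  rates <- setNames(unname(fm$net[rate_rxn]), rate_rxn)
  generate_mids(net, fm, mix_fit, noise_sd = noise_sd, n_replicates = 2,
                seed = seed, fragments = frag, rates = rates,
                rate_sd_rel = rate_sd_rel)
}

test_that("profile intervals nest (68% inside 95%) and cover a toy truth", {
  net <- toy_split_permute()
  frag <- data.frame(fragment = "D", emu = "D|1,2,3", size = 3L)
  fm <- flux_map(c(p1 = 0.6, p2 = 0.4, j1 = 0.6, j2 = 0.4, out = 1),
                 model = net)
  ms <- toy_measurements(net, fm, frag, 0.004, 3, "out")
  fit <- suppressWarnings(
    fit_fluxes(net, ms, mix_fit, fit_config(restarts = 3, seed = 5)))
  ci95 <- confidence_intervals(fit, "p1", level = 0.95)
  ci68 <- confidence_intervals(fit, "p1", level = 0.68)
  expect_lte(ci95[1, "lower"], ci68[1, "lower"])
  expect_gte(ci95[1, "upper"], ci68[1, "upper"])
  expect_lte(ci68[1, "lower"], fit$fluxes$net[["p1"]])
  expect_gte(ci68[1, "upper"], fit$fluxes$net[["p1"]])
  # with this noise level the 95% interval spans the truth comfortably
  expect_lte(ci95[1, "lower"], 0.6 + 0.2)
  expect_gte(ci95[1, "upper"], 0.6 - 0.2)
})

test_that("a structurally non-identifiable split yields an open-ended
           interval, not an error", {
  net <- toy_parallel()
  frag <- data.frame(fragment = "B", emu = "B|1,2,3", size = 3L)
  fm <- flux_map(c(p1 = 0.5, p2 = 0.5, out = 1), model = net)
  ms <- toy_measurements(net, fm, frag, 0.004, 4, "out")
  fit <- suppressWarnings(
    fit_fluxes(net, ms, mix_fit, fit_config(restarts = 2, seed = 6)))
  ci <- suppressWarnings(
    confidence_intervals(fit, "p1", level = 0.95, max_range = 3))
  # p1 can absorb the whole throughput on the upper side
  expect_true(is.infinite(ci[1, "upper"]) || ci[1, "upper"] > 1)
  expect_lte(ci[1, "lower"], 0.1)
})

test_that("under-determined configurations warn about rank deficiency", {
  net <- toy_parallel()
  frag <- data.frame(fragment = "B", emu = "B|1,2,3", size = 3L)
  fm <- flux_map(c(p1 = 0.5, p2 = 0.5, out = 1), model = net)
  ms <- toy_measurements(net, fm, frag, 0.004, 4, "out")
  expect_warning(
    fit_fluxes(net, ms, mix_fit, fit_config(restarts = 2, seed = 6)),
    "rank-deficient|non-identifiable")
})

test_that("fit methods expose fluxes, simulated MIDs and residuals", {
  net <- toy_split_permute()
  frag <- data.frame(fragment = "D", emu = "D|1,2,3", size = 3L)
  fm <- flux_map(c(p1 = 0.6, p2 = 0.4, j1 = 0.6, j2 = 0.4, out = 1),
                 model = net)
  ms <- toy_measurements(net, fm, frag, 0.004, 8, "out")
  fit <- suppressWarnings(
    fit_fluxes(net, ms, mix_fit, fit_config(restarts = 2, seed = 9)))
  expect_named(coef(fit), names(net$reactions), ignore.order = TRUE)
  pred <- predict(fit)
  expect_equal(sum(pred[["D|1,2,3"]]), 1, tolerance = 1e-9)
  expect_equal(length(residuals(fit)), fit$prob$n_meas)
  s <- summary(fit)
  expect_s3_class(s, "summary.flux_fit")
  expect_null(s$splits)           # toy model has no central-carbon splits
  expect_output(print(fit), "SSR")
})
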