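# Synthetic study conditions: ground-truth flux maps, noisy MID
# measurement sets, and batch fermentation time courses with the
# statistical structure the estimators assume.

#' Scenario configuration for synthetic data
#'
#' Bundles the study conditions of one batch fermentation.  The `"H"`
#' (high dissolved oxygen) and `"L"` (low DO) profiles default to the
#' measured kinetic parameters of the two batch modes: specific glucose
#' uptake 5.32 / 5.66 mmol/gDCW/h, riboflavin production 0.054 / 0.038
#' g/gDCW/h, growth rate 0.092 / 0.035 1/h, biomass yield 0.096 / 0.034
#' gDCW/gGlc, OUR 10.02 / 4.56 and CER 9.52 / 4.47 mmol/gDCW/h, and
#' oxidative-PP / TCA pathway splits of 64.85 / 7.50 (H) and 50.79 /
#' 12.08 (L) percent of glucose uptake.
#'
#' @param profile `"H"`, `"L"`, or `"custom"`.
#' @param seed integer seed controlling every random element downstream.
#' @param ... overrides for any field (`qGlc`, `qRib`, `mu`, `Yxs`, `OUR`,
#'   `CER`, `pp_split`, `tca_split`, `lac_share`, `mid_noise_sd`,
#'   `n_replicates`, `exch_lo`, `exch_hi`, `time_grid`, `X0`, `S0`,
#'   `tc_noise_sd`).
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(profile = c("H", "L", "custom"), seed = 1L, ...) {
  profile <- match.arg(profile)
  base <- switch(profile,
    H = list(qGlc = 5.32, qRib = 0.054, mu = 0.092, Yxs = 0.096,
             OUR = 10.02, CER = 9.52, pp_split = 64.85, tca_split = 7.50),
    L = list(qGlc = 5.66, qRib = 0.038, mu = 0.035, Yxs = 0.034,
             OUR = 4.56, CER = 4.47, pp_split = 50.79, tca_split = 12.08),
    custom = list(qGlc = 5, qRib = 0.04, mu = 0.05, Yxs = 0.05,
                  OUR = 5, CER = 5, pp_split = 50, tca_split = 10))
  cfg <- utils::modifyList(
    c(base, list(profile = profile, seed = as.integer(seed),
                 lac_share = 0.6, mid_noise_sd = 0.004, n_replicates = 2L,
                 exch_lo = 0.05, exch_hi = 0.25,
                 time_grid = seq(0, 44, by = 2), X0 = 0.10, S0 = 40,
                 tc_noise_sd = 0)),
    list(...))
  if (cfg$mid_noise_sd <= 0) stop("mid_noise_sd must be > 0", call. = FALSE)
  structure(cfg, class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "Scenario '%s' (seed %d): qGlc %.2f, qRib %.3f, mu %.3f, PP %.2f%%, TCA %.2f%%\n",
    x$profile, x$seed, x$qGlc, x$qRib, x$mu, x$pp_split, x$tca_split))
  invisible(x)
}

#' Riboflavin molar mass and carbon count
#' @keywords internal
RIB_MW <- 376.36
RIB_C <- 17L
GLC_MW <- 180.16

#' Solve for a ground-truth flux map under a scenario
#'
#' Constructs the steady-state flux map with glucose uptake `qGlc`,
#' oxidative-PP split (`zwf` flux) at `pp_split` percent of uptake, TCA
#' entry (`cs`) at `tca_split` percent, biomass flux equal to `mu`, and a
#' riboflavin drain matching `qRib`; the remaining overflow degree of
#' freedom is divided between lactate and acetate by `lac_share` (mole
#' fraction of overflow pyruvate routed to lactate).  Exchange fluxes of
#' reversible reactions are drawn reproducibly from the seed, uniformly
#' between `exch_lo` and `exch_hi` times the glucose uptake (moderate
#' equilibration; strongly equilibrated exchange degrades the
#' identifiability of the pathway splits, see the methods vignette).
#' If the
#' requested set-points are infeasible the least-squares nearest
#' steady-state map is returned with a `distance` attribute.
#'
#' @param model a `flux_network` (the default network).
#' @param scenario a [scenario_config()].
#' @return a [flux_map()]; `attr(, "distance")` is 0 for feasible
#'   set-points.
#' @export
generate_flux_map <- function(model, scenario) {
  S <- stoichiometric_matrix(model)
  rn <- colnames(S)
  qRib_mmol <- scenario$qRib / RIB_MW * 1000
  pin1 <- c(upt = scenario$qGlc,
            zwf = scenario$pp_split / 100 * scenario$qGlc,
            cs = scenario$tca_split / 100 * scenario$qGlc,
            biomass = scenario$mu,
            rib_syn = qRib_mmol,
            ldh = 0)
  solve_pinned <- function(pins) {
    E <- matrix(0, length(pins), length(rn),
                dimnames = list(names(pins), rn))
    for (nm in names(pins)) E[nm, nm] <- 1
    A <- rbind(S, E)
    b <- c(rep(0, nrow(S)), pins)
    v <- qr.solve(A, b)
    names(v) <- rn
    attr(v, "distance") <- sqrt(sum((A %*% v - b)^2))
    v
  }
  v0 <- solve_pinned(pin1)
  overflow <- v0[["ack"]] + v0[["ldh"]]
  pin1["ldh"] <- scenario$lac_share * max(overflow, 0)
  v <- solve_pinned(pin1)
  rev <- rn[vapply(model$reactions, `[[`, TRUE, "reversible")]
  set.seed(scenario$seed)
  exch <- setNames(scenario$qGlc *
                     stats::runif(length(rev), scenario$exch_lo,
                                  scenario$exch_hi), rev)
  fm <- flux_map(v, exch, model = model)
  attr(fm, "distance") <- attr(v, "distance")
  if (attr(v, "distance") > 1e-6)
    warning("requested set-points are infeasible; returning nearest ",
            "steady-state map (distance ",
            format(attr(v, "distance"), digits = 3), ")")
  irr <- rn[!vapply(model$reactions, `[[`, TRUE, "reversible")]
  if (any(v[irr] < -1e-9))
    warning("generated map carries negative irreversible flux(es): ",
            paste(irr[v[irr] < -1e-9], collapse = ", "))
  fm
}

#' Generate a noisy MID measurement set from a flux map
#'
#' Simulates the fragment MIDs, then adds independent Gaussian noise per
#' mass channel (the standard GC-MS MID error treatment), clips at zero
#' and renormalizes each replicate to sum 1.
#'
#' @param model,fluxmap,mixture as in [simulate_mids()].
#' @param noise_sd additive noise standard deviation per mass channel
#'   (mol fraction); values >= 0.2 are refused as non-physical.
#' @param n_replicates number of labeling replicates.
#' @param seed integer seed.
#' @param fragments fragment table as from [default_fragments()].
#' @param rates optional named vector of external rates to attach as
#'   constraints (`qGlc`, `qRib`, `mu`), with default relative sd 1%.
#' @param rate_sd_rel relative standard deviation of rate constraints.
#' @return a [measurement_set()].
#' @export
generate_mids <- function(model, fluxmap, mixture, noise_sd = 0.004,
                          n_replicates = 2L, seed = 1L,
                          fragments = default_fragments(),
                          rates = NULL, rate_sd_rel = 0.01) {
  if (noise_sd >= 0.2)
    stop("noise_sd >= 0.2 mol fraction is non-physical", call. = FALSE)
  clean <- simulate_fragments(model, fluxmap, mixture, fragments$emu)
  set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(fragments))) {
    mid <- clean[[fragments$emu[i]]]
    for (rep_i in seq_len(n_replicates)) {
      noisy <- mid + stats::rnorm(length(mid), 0, noise_sd)
      noisy[noisy < 0] <- 0
      noisy <- noisy / sum(noisy)
      rows[[length(rows) + 1L]] <- data.frame(
        fragment = fragments$fragment[i], emu = fragments$emu[i],
        replicate = rep_i, mass = seq_along(mid) - 1L,
        value = noisy, sd = noise_sd, stringsAsFactors = FALSE)
    }
  }
  mids <- do.call(rbind, rows)
  rates_df <- NULL
  if (!is.null(rates))
    rates_df <- data.frame(quantity = names(rates), value = unname(rates),
                           sd = abs(unname(rates)) * rate_sd_rel,
                           stringsAsFactors = FALSE)
  measurement_set(mids, rates_df)
}

#' Generate a batch fermentation time course
#'
#' Exponential growth from inoculum `X0` at rate `mu`; glucose consumed at
#' yield `Yxs` from `S0` and truncated (with a `depleted` flag) once
#' exhausted; riboflavin accumulating in proportion to biomass formed at
#' specific rate `qRib`.  The dissolved-oxygen trace is high (40%) for the
#' first 24 h, then stays at 35% for the H profile or drops below 10% for
#' the L profile.  Three sampling-phase labels mark early, transition and
#' late process phases.  Optional multiplicative log-normal noise of
#' relative sd `tc_noise_sd` applies to DCW, glucose and riboflavin.
#'
#' @param scenario a [scenario_config()].
#' @return data frame of class `timecourse` with columns `time`, `DCW`,
#'   `glucose`, `riboflavin`, `DO`, `CER`, `OUR`, `phase`;
#'   `attr(, "depleted")` flags glucose exhaustion before the end of the
#'   grid.
#' @export
generate_timecourse <- function(scenario) {
  stopifnot(scenario$mu > 0, scenario$Yxs > 0)
  t <- scenario$time_grid
  X <- scenario$X0 * exp(scenario$mu * t)
  S <- scenario$S0 - (X - scenario$X0) / scenario$Yxs
  P <- scenario$qRib / scenario$mu * (X - scenario$X0)
  depleted <- any(S <= 0)
  if (depleted) {
    keep <- S > 0
    t <- t[keep]; X <- X[keep]; S <- S[keep]; P <- P[keep]
  }
  DO <- ifelse(t <= 24, 40,
               if (scenario$profile == "L") 5 else 35)
  if (scenario$tc_noise_sd > 0) {
    set.seed(scenario$seed + 1L)
    jitter <- function(x) x * exp(stats::rnorm(length(x), 0,
                                               scenario$tc_noise_sd))
    X <- jitter(X); S <- jitter(S); P <- jitter(P)
  }
  tc <- data.frame(time = t, DCW = X, glucose = S, riboflavin = P,
                   DO = DO, CER = scenario$CER, OUR = scenario$OUR,
                   phase = cut(t, c(-Inf, 24, 36, Inf), labels = 1:3))
  class(tc) <- c("timecourse", "data.frame")
  attr(tc, "depleted") <- depleted
  tc
}
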