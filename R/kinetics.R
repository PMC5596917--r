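# Batch fermentation kinetics (specific rates, yields, respiratory
# quotient), carbon balance / recovery, and metabolite pool comparison.

GLC_C <- 6L

#' Molecular formulas used in carbon-rate conversions
#' @keywords internal
species_info <- function(species) {
  switch(species,
         glucose = list(mw = GLC_MW, carbons = GLC_C),
         riboflavin = list(mw = RIB_MW, carbons = RIB_C),
         lactate = list(mw = 90.08, carbons = 3L),
         acetate = list(mw = 60.05, carbons = 2L),
         acetoin = list(mw = 88.11, carbons = 4L),
         co2 = list(mw = 44.01, carbons = 1L),
         stop("unknown species '", species,
              "'; supply mw and carbons explicitly", call. = FALSE))
}

#' Specific rates and yields from a batch time course
#'
#' Over the chosen time window: the specific growth rate is the
#' least-squares slope of log biomass versus time; the biomass yield is
#' the slope of biomass formed versus glucose consumed; the specific
#' glucose uptake rate is `mu / Y_X/S` converted to mmol/gDCW/h with the
#' anhydrous glucose molar mass (180.16 g/mol); the specific riboflavin
#' production rate is the slope of product versus biomass times `mu`
#' (g/gDCW/h).  The default window is the post-24 h phase, where the two
#' dissolved-oxygen regimes diverge.
#'
#' @param tc a time-course data frame (see [generate_timecourse()]) with
#'   at least `time`, `DCW`, `glucose`; optionally `riboflavin`, `CER`,
#'   `OUR`.
#' @param window numeric length-2 time interval (h); defaults to
#'   24 h .. end.
#' @return object of class `rates_table`: `mu` (1/h), `Yxs` (gDCW/gGlc),
#'   `qGlc` (mmol/gDCW/h), `qRib` (g/gDCW/h), `Yps` (gRib/gGlc), and,
#'   when CER/OUR columns are present, their window means and `RQ`.
#' @export
specific_rates <- function(tc, window = NULL) {
  if (is.null(window)) window <- c(24, max(tc$time))
  w <- tc$time >= window[1] & tc$time <= window[2]
  if (sum(w) < 3) stop("need at least 3 points in the window", call. = FALSE)
  t <- tc$time[w]; X <- tc$DCW[w]; S <- tc$glucose[w]
  if (any(X <= 0)) stop("non-positive biomass in window", call. = FALSE)
  mu <- unname(stats::coef(stats::lm(log(X) ~ t))[2])
  dS <- S[1] - S
  if (utils::tail(dS, 1) < 0)
    warning("glucose increases over the window; negative uptake rate")
  Yxs <- unname(stats::coef(stats::lm(I(X - X[1]) ~ 0 + dS))[1])
  qGlc <- mu / Yxs / GLC_MW * 1000
  qRib <- Yps <- NA_real_
  if ("riboflavin" %in% names(tc)) {
    P <- tc$riboflavin[w]
    Ypx <- unname(stats::coef(stats::lm(I(P - P[1]) ~ 0 + I(X - X[1])))[1])
    qRib <- Ypx * mu                       # g Rib / gDCW / h
    Yps <- Ypx * Yxs                       # g Rib / g Glc
  }
  out <- list(mu = mu, Yxs = Yxs, qGlc = qGlc, qRib = qRib, Yps = Yps,
              window = window)
  if (all(c("CER", "OUR") %in% names(tc))) {
    out$CER <- mean(tc$CER[w]); out$OUR <- mean(tc$OUR[w])
    out$RQ <- respiratory_quotient(out$CER, out$OUR)
  }
  structure(out, class = "rates_table")
}

#' @export
print.rates_table <- function(x, ...) {
  cat(sprintf("Window %g-%g h: mu = %.4f 1/h, Y_X/S = %.4f gDCW/gGlc, ",
              x$window[1], x$window[2], x$mu, x$Yxs))
  cat(sprintf("qGlc = %.2f mmol/gDCW/h, qRib = %.4f g/gDCW/h\n",
              x$qGlc, x$qRib))
  if (!is.null(x$RQ)) cat(sprintf("CER = %.2f, OUR = %.2f, RQ = %.2f\n",
                                  x$CER, x$OUR, x$RQ))
  invisible(x)
}

#' Respiratory quotient
#'
#' @param cer carbon dioxide evolution rate (mmol/gDCW/h).
#' @param our oxygen uptake rate (mmol/gDCW/h, > 0).
#' @param digits decimals in the reported value (tables print 2).
#' @return RQ = CER/OUR, rounded to `digits`.
#' @export
respiratory_quotient <- function(cer, our, digits = 2) {
  if (!is.numeric(our) || any(our <= 0))
    stop("OUR must be > 0", call. = FALSE)
  round(cer / our, digits)
}

#' Convert a specific rate to a carbon rate
#'
#' Rates in mmol/gDCW/h are multiplied by the species carbon number;
#' rates in g/gDCW/h are first divided by the molar mass (g/mol, x 1000
#' for mmol).  Glucose uses the anhydrous molar mass 180.16 and 6
#' carbons; riboflavin C17H20N4O6 uses 376.36 and 17 carbons.
#'
#' @param q specific rate.
#' @param species one of `"glucose"`, `"riboflavin"`, `"lactate"`,
#'   `"acetate"`, `"acetoin"`, `"co2"`, or `NULL` when `mw`/`carbons`
#'   are given.
#' @param unit `"mmol"` (mmol/gDCW/h) or `"g"` (g/gDCW/h).
#' @param mw,carbons explicit molar mass and carbon count overriding the
#'   species table.
#' @return carbon rate, mmolC/gDCW/h.
#' @export
carbon_rate_from_mass_rate <- function(q, species = NULL, unit = "mmol",
                                       mw = NULL, carbons = NULL) {
  if (is.null(mw) || is.null(carbons)) {
    if (is.null(species))
      stop("unknown species: supply species or mw + carbons", call. = FALSE)
    info <- species_info(species)
    mw <- mw %||% info$mw
    carbons <- carbons %||% info$carbons
  }
  switch(unit,
         mmol = q * carbons,
         g = q / mw * 1000 * carbons,
         stop("unit must be 'mmol' or 'g'", call. = FALSE))
}

#' Carbon balance and recovery of a labeling experiment
#'
#' Recovery is the percentage of consumed glucose carbon accounted for by
#' biomass, CO2 (CER), riboflavin and by-products:
#' `100 * (biomass + cer + riboflavin + byproducts) / glucose`.
#'
#' @param glucose carbon uptake rate, mmolC/gDCW/h (> 0); alternatively
#'   supply `qGlc` (mmol/gDCW/h) and the conversion by 6 carbons is done
#'   here.
#' @param biomass,cer,riboflavin,byproducts output carbon rates,
#'   mmolC/gDCW/h; all required (0 is allowed, missing is not).
#' @param qGlc optional specific glucose uptake rate used when `glucose`
#'   is not given.
#' @param digits decimals of the reported recovery (tables print 2).
#' @return object of class `carbon_balance` with the rates and
#'   `recovery` (%).
#' @export
carbon_balance <- function(glucose = NULL, biomass, cer, riboflavin,
                           byproducts, qGlc = NULL, digits = 2) {
  if (is.null(glucose)) {
    if (is.null(qGlc)) stop("supply glucose (mmolC) or qGlc (mmol)",
                            call. = FALSE)
    glucose <- carbon_rate_from_mass_rate(qGlc, "glucose")
  }
  vals <- c(biomass = biomass, cer = cer, riboflavin = riboflavin,
            byproducts = byproducts)
  missing <- names(vals)[is.na(vals)]
  if (length(missing))
    stop("missing carbon rate component(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (glucose <= 0) stop("glucose carbon input must be > 0", call. = FALSE)
  if (any(vals < 0)) stop("carbon rates must be >= 0", call. = FALSE)
  rec <- round(100 * sum(vals) / glucose, digits)
  structure(list(glucose = glucose, rates = vals, recovery = rec),
            class = "carbon_balance")
}

#' @export
print.carbon_balance <- function(x, ...) {
  cat("Carbon balance (mmolC/gDCW/h):\n")
  cat(sprintf("  glucose in  %.2f\n", x$glucose))
  for (nm in names(x$rates))
    cat(sprintf("  %-11s %.2f\n", nm, x$rates[[nm]]))
  cat(sprintf("  recovery    %.2f%%\n", x$recovery))
  invisible(x)
}

#' Compare metabolite pool sizes between two conditions
#'
#' Per metabolite: fold change (B over A), two-sided Welch t-test P value
#' and a significance flag at the chosen level.
#'
#' @param groupA,groupB numeric matrices or data frames (replicates x
#'   metabolites, same column names) or numeric vectors for a single
#'   metabolite.
#' @param alpha significance level for the flag (default 0.05).
#' @return data frame with `metabolite`, `fold_change`, `direction`,
#'   `p_value`, `significant`.
#' @export
pool_compare <- function(groupA, groupB, alpha = 0.05) {
  if (is.vector(groupA)) groupA <- matrix(groupA, ncol = 1,
                                          dimnames = list(NULL, "pool"))
  if (is.vector(groupB)) groupB <- matrix(groupB, ncol = 1,
                                          dimnames = list(NULL, "pool"))
  groupA <- as.matrix(groupA); groupB <- as.matrix(groupB)
  stopifnot(identical(colnames(groupA), colnames(groupB)))
  if (nrow(groupA) < 2 || nrow(groupB) < 2)
    stop("need >= 2 replicates per group", call. = FALSE)
  res <- lapply(colnames(groupA), function(m) {
    a <- groupA[, m]; b <- groupB[, m]
    p <- if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    } else stats::t.test(a, b)$p.value
    data.frame(metabolite = m,
               fold_change = mean(b) / mean(a),
               direction = sign(mean(b) - mean(a)),
               p_value = p,
               significant = p < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# ---- rates / timecourse IO ---------------------------------------------

#' Read and write rate tables and time courses
#'
#' Rate tables are YAML mappings (quantity: value or quantity: [value,
#' sd]); time courses are plain CSV.
#'
#' @param x named list / vector (rates) or data frame (time course).
#' @param path file path.
#' @return readers return the parsed object.
#' @export
write_rates <- function(x, path) {
  yaml::write_yaml(as.list(x), path)
  invisible(path)
}

#' @rdname write_rates
#' @export
read_rates <- function(path) yaml::read_yaml(path)

#' @rdname write_rates
#' @export
write_timecourse <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_rates
#' @export
read_timecourse <- function(path) {
  tc <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(tc) <- c("timecourse", "data.frame")
  tc
}
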