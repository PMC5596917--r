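# ---- tracer ------------------------------------------------------------

#' Define a 13C tracer mixture
#'
#' A mixture is a set of glucose species, each with a per-carbon-position
#' probability of being 13C and a molar fraction.  The default is the
#' labeling experiment mixture: 30% natural-abundance glucose, 20%
#' [1-13C]-glucose and 50% [U-13C]-glucose.
#'
#' @param fractions named numeric vector of molar fractions summing to 1.
#'   Recognised component names are `natural`, `c1` ([1-13C]) and
#'   `uniform` ([U-13C]); arbitrary components can be given via `patterns`.
#' @param natural_abundance 13C probability per carbon position of the
#'   natural component (default 0.0107).
#' @param patterns optional named list of length-6 per-position 13C
#'   probability vectors overriding/extending the built-ins.
#' @return object of class `tracer_mixture`.
#' @export
tracer_mixture <- function(fractions = c(natural = 0.30, c1 = 0.20,
                                         uniform = 0.50),
                           natural_abundance = 0.0107,
                           patterns = NULL) {
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("tracer component fractions must sum to 1", call. = FALSE)
  built_in <- list(natural = rep(natural_abundance, 6),
                   c1 = c(1, 0, 0, 0, 0, 0),
                   uniform = rep(1, 6))
  pats <- utils::modifyList(built_in, as.list(patterns %||% list()))
  missing <- setdiff(names(fractions), names(pats))
  if (length(missing))
    stop("no labeling pattern for component(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (p in pats[names(fractions)])
    if (length(p) != 6L || any(p < 0 | p > 1))
      stop("labeling patterns must be 6 probabilities in [0,1]",
           call. = FALSE)
  structure(list(fractions = fractions,
                 patterns = pats[names(fractions)],
                 natural_abundance = natural_abundance),
            class = "tracer_mixture")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.tracer_mixture <- function(x, ...) {
  cat("13C tracer mixture:\n")
  for (nm in names(x$fractions))
    cat(sprintf("  %-8s %5.1f%%  positions: %s\n", nm,
                100 * x$fractions[[nm]],
                paste(format(x$patterns[[nm]], digits = 3), collapse = " ")))
  invisible(x)
}

# Poisson-binomial mass distribution over independent positions.
position_mid <- function(p) {
  out <- 1
  for (pi in p) out <- convolve_mid(out, c(1 - pi, pi))
  out
}

convolve_mid <- function(a, b) {
  n <- length(a) + length(b) - 1L
  out <- numeric(n)
  for (i in seq_along(a)) out[i:(i + length(b) - 1L)] <-
      out[i:(i + length(b) - 1L)] + a[i] * b
  out
}

#' Mass isotopomer distribution of a substrate-glucose fragment
#'
#' Computes the MID of a subset of glucose carbon positions under a tracer
#' mixture: within each component, positions label independently, so the
#' component MID is the Poisson-binomial convolution of the per-position
#' probabilities; component MIDs mix by molar fraction.
#'
#' @param mixture a [tracer_mixture()].
#' @param positions integer vector of glucose carbon positions (1-based).
#' @return numeric MID vector of length `length(positions) + 1`.
#' @export
glucose_input_mid <- function(mixture, positions = 1:6) {
  stopifnot(inherits(mixture, "tracer_mixture"))
  if (length(positions) == 0L || any(positions < 1 | positions > 6))
    stop("positions must be a non-empty subset of 1..6", call. = FALSE)
  mid <- numeric(length(positions) + 1L)
  for (nm in names(mixture$fractions))
    mid <- mid + mixture$fractions[[nm]] *
      position_mid(mixture$patterns[[nm]][positions])
  mid
}

# ---- EMU decomposition --------------------------------------------------

emu_key <- function(met, atoms) paste0(met, "|", paste(sort(atoms), collapse = ","))
emu_met <- function(key) sub("\\|.*$", "", key)
emu_atoms <- function(key) as.integer(strsplit(sub("^.*\\|", "", key), ",")[[1]])

#' Decompose a network into the EMU system needed for target fragments
#'
#' Starting from target elementary metabolite units (EMUs), traces product
#' carbons back through every producing reaction (including backward
#' directions of reversible reactions and scrambling alternatives) to the
#' minimal closed set of EMUs whose balances determine the targets,
#' grouped by EMU size.  Where a product EMU spans carbons of two or more
#' substrate molecules, the producing term is a convolution of smaller
#' EMUs.
#'
#' @param model a `flux_network`.
#' @param targets character vector of EMU keys (`"Met|i,j,k"`) or a list of
#'   `list(met =, atoms =)`.
#' @return object of class `emu_system`: per-size levels, each with the
#'   unknown EMUs of that size and the producing terms feeding them.
#' @export
emu_decompose <- function(model, targets) {
  if (is.list(targets) && !is.character(targets))
    targets <- vapply(targets, function(t) emu_key(t$met, t$atoms), "")
  role <- setNames(model$metabolites$role, model$metabolites$id)
  for (key in targets) {
    m <- emu_met(key); a <- emu_atoms(key)
    if (!m %in% names(role))
      stop("target EMU on unknown metabolite: ", m, call. = FALSE)
    if (length(a) == 0L || any(a < 1 | a > model$carbons[m]))
      stop("invalid atom set for EMU ", key, call. = FALSE)
  }
  variants <- network_variants(model)
  # index variants by product metabolite
  by_prod <- list()
  for (vi in seq_along(variants))
    for (m in unique(variants[[vi]]$prods))
      by_prod[[m]] <- c(by_prod[[m]], vi)

  seen <- character()
  terms <- list()                    # per unknown emu: list of producing terms
  queue <- unique(targets)
  while (length(queue)) {
    key <- queue[[1]]; queue <- queue[-1]
    if (key %in% seen) next
    seen <- c(seen, key)
    m <- emu_met(key)
    if (role[[m]] != "balanced") next          # inputs terminate the trace
    atoms <- emu_atoms(key)
    prod_terms <- list()
    for (vi in by_prod[[m]] %||% integer()) {
      v <- variants[[vi]]
      for (p in which(v$prods == m)) {
        a <- v$assign[[p]][atoms, , drop = FALSE]
        src <- split(a[, "pos"], a[, "sub"])
        sources <- vapply(names(src), function(si)
          emu_key(v$subs[as.integer(si)], src[[si]]), "")
        prod_terms[[length(prod_terms) + 1L]] <- list(
          rxn = v$rxn, dir = v$dir, weight = v$weight,
          sources = unname(sources))
        queue <- c(queue, unname(sources))
      }
    }
    if (length(prod_terms) == 0L)
      stop("EMU ", key, " on a balanced metabolite has no producing ",
           "reaction (unreachable from the substrate)", call. = FALSE)
    terms[[key]] <- prod_terms
  }
  unknown <- names(terms)
  sizes <- vapply(unknown, function(k) length(emu_atoms(k)), 1L)
  levels <- lapply(sort(unique(sizes)), function(s) {
    list(size = s, emus = unknown[sizes == s],
         terms = terms[unknown[sizes == s]])
  })
  out <- structure(list(levels = levels, targets = targets,
                        n_emu = length(unknown)),
                   class = "emu_system")
  compile_emu_system(out, model)
}

# Precompile the balance assembly: flux slots, consumption matrix, and
# per-level index structures, so repeated simulations only do numeric work.
compile_emu_system <- function(sys, model) {
  role <- setNames(model$metabolites$role, model$metabolites$id)
  flux_keys <- character()
  for (r in model$reactions) {
    if (r$drain) { flux_keys <- c(flux_keys, paste0("d:", r$id)); next }
    flux_keys <- c(flux_keys, paste0("f:", r$id))
    if (r$reversible) flux_keys <- c(flux_keys, paste0("b:", r$id))
  }
  slot <- setNames(seq_along(flux_keys), flux_keys)
  mets <- model$metabolites$id
  Cons <- matrix(0, length(mets), length(flux_keys),
                 dimnames = list(mets, flux_keys))
  for (r in model$reactions) {
    if (r$drain) {
      for (k in seq_len(nrow(r$sub)))
        Cons[r$sub$id[k], paste0("d:", r$id)] <-
          Cons[r$sub$id[k], paste0("d:", r$id)] + r$sub$coef[k]
      next
    }
    for (m in r$sub_inst)
      Cons[m, paste0("f:", r$id)] <- Cons[m, paste0("f:", r$id)] + 1
    if (r$reversible)
      for (m in r$prod_inst)
        Cons[m, paste0("b:", r$id)] <- Cons[m, paste0("b:", r$id)] + 1
  }
  term_key <- function(t) paste0(if (t$dir > 0) "f:" else "b:", t$rxn)
  compiled <- lapply(sys$levels, function(lv) {
    n <- length(lv$emus)
    idx <- setNames(seq_len(n), lv$emus)
    ai <- aj <- as_ <- aw <- integer(0); aw <- numeric(0)
    b_i <- integer(0); b_slot <- integer(0); b_w <- numeric(0)
    b_src <- list()
    for (i in seq_len(n)) {
      for (t in lv$terms[[lv$emus[i]]]) {
        sl <- slot[[term_key(t)]]
        if (length(t$sources) == 1L && t$sources %in% lv$emus) {
          ai <- c(ai, i); aj <- c(aj, idx[[t$sources]])
          as_ <- c(as_, sl); aw <- c(aw, t$weight)
        } else {
          b_i <- c(b_i, i); b_slot <- c(b_slot, sl)
          b_w <- c(b_w, t$weight)
          b_src[[length(b_src) + 1L]] <- t$sources
        }
      }
    }
    gid <- if (length(ai)) match(paste(ai, aj), unique(paste(ai, aj))) else integer()
    uij <- if (length(ai)) cbind(ai, aj)[!duplicated(paste(ai, aj)), ,
                                         drop = FALSE] else cbind(ai, aj)
    list(size = lv$size, emus = lv$emus,
         met_idx = match(vapply(lv$emus, emu_met, ""), mets),
         ai = ai, aj = aj, a_slot = as_, a_w = aw, a_gid = gid, a_uij = uij,
         b_i = b_i, b_slot = b_slot, b_w = b_w, b_src = b_src)
  })
  sys$compiled <- compiled
  sys$flux_keys <- flux_keys
  sys$Cons <- Cons
  sys$role <- role
  sys
}

#' @export
print.emu_system <- function(x, ...) {
  cat("EMU system:", x$n_emu, "unknown EMUs in", length(x$levels),
      "size levels\n")
  for (lv in x$levels)
    cat(sprintf("  size %d: %d EMUs\n", lv$size, length(lv$emus)))
  invisible(x)
}

# ---- flux maps ----------------------------------------------------------

#' Construct a flux map
#'
#' @param net named numeric vector of net fluxes (mmol/gDCW/h), one per
#'   reaction of the model.
#' @param exch named numeric vector of exchange fluxes (>= 0) for reversible
#'   reactions; missing reversible reactions get exchange 0.
#' @param model the `flux_network` the map belongs to (names are checked).
#' @return object of class `flux_map`.
#' @export
flux_map <- function(net, exch = NULL, model = NULL) {
  if (!is.null(model)) {
    if (!setequal(names(net), names(model$reactions)))
      stop("net flux names must match the model's reactions", call. = FALSE)
    net <- net[names(model$reactions)]
    rev <- names(model$reactions)[vapply(model$reactions, `[[`, TRUE,
                                         "reversible")]
    full <- setNames(numeric(length(rev)), rev)
    if (!is.null(exch)) {
      bad <- setdiff(names(exch), rev)
      if (length(bad))
        stop("exchange flux on irreversible reaction(s): ",
             paste(bad, collapse = ", "), call. = FALSE)
      full[names(exch)] <- exch
    }
    exch <- full
  }
  if (any(exch < 0)) stop("exchange fluxes must be >= 0", call. = FALSE)
  structure(list(net = net, exch = exch %||% numeric()), class = "flux_map")
}

#' @export
print.flux_map <- function(x, ...) {
  cat("Flux map (mmol/gDCW/h):\n")
  print(round(x$net, 4))
  if (length(x$exch)) {
    cat("exchange:\n"); print(round(x$exch, 4))
  }
  invisible(x)
}

# Unidirectional flux of one reaction direction given net + exchange.
directed_flux <- function(fluxmap, rxn, dir) {
  v <- fluxmap$net[[rxn]]
  e <- if (rxn %in% names(fluxmap$exch)) fluxmap$exch[[rxn]] else 0
  if (dir > 0) e + max(v, 0) else e + max(-v, 0)
}

# ---- EMU simulation -----------------------------------------------------

#' Simulate mass isotopomer distributions from a flux map
#'
#' Solves the EMU balance system level by level (ascending EMU size): at
#' each size the unknown MIDs satisfy a linear system whose inputs are the
#' tracer MIDs and convolutions of smaller EMUs already solved.  MIDs are
#' invariant to a global rescaling of all fluxes.
#'
#' @param model a `flux_network`.
#' @param fluxmap a [flux_map()]; net fluxes must satisfy steady state.
#' @param mixture a [tracer_mixture()] defining the substrate labeling.
#' @param targets EMU keys (see [emu_decompose()]); defaults to the full
#'   carbon skeletons of the measured amino-acid precursors.
#' @param decomp optional pre-computed [emu_decompose()] result (re-use it
#'   across many simulations of the same target set for speed).
#' @return named list mapping each requested EMU key to its MID vector.
#' @export
simulate_mids <- function(model, fluxmap, mixture,
                          targets = default_fragments()$emu,
                          decomp = NULL) {
  if (is.null(decomp)) decomp <- emu_decompose(model, targets)

  # unidirectional flux per slot ("f:rxn", "b:rxn", "d:rxn")
  fk <- decomp$flux_keys
  kind <- substr(fk, 1, 1)
  rxn <- substring(fk, 3)
  net <- fluxmap$net[rxn]
  exch <- unname(fluxmap$exch[rxn])
  exch[is.na(exch)] <- 0
  fluxvec <- ifelse(kind == "f", exch + pmax(net, 0),
                    ifelse(kind == "b", exch + pmax(-net, 0), net))
  names(fluxvec) <- fk
  cons <- drop(decomp$Cons %*% fluxvec)

  mids <- new.env(parent = emptyenv())
  get_mid <- function(key) {
    v <- mids[[key]]
    if (!is.null(v)) return(v)
    m <- emu_met(key)
    if (decomp$role[[m]] == "substrate") {
      out <- glucose_input_mid(mixture, emu_atoms(key))
      mids[[key]] <- out
      return(out)
    }
    stop("internal: EMU ", key, " requested before being solved")
  }

  for (lv in decomp$compiled) {
    n <- length(lv$emus)
    A <- matrix(0, n, n)
    diag(A) <- -cons[lv$met_idx]
    if (length(lv$ai)) {
      vals <- fluxvec[lv$a_slot] * lv$a_w
      sums <- rowsum(vals, lv$a_gid)
      A[lv$a_uij] <- A[lv$a_uij] + sums[, 1]   # rowsum sorts gid 1..K
    }
    B <- matrix(0, n, lv$size + 1L)
    if (length(lv$b_i)) {
      conv_cache <- new.env(parent = emptyenv())
      for (t in seq_along(lv$b_i)) {
        f <- fluxvec[lv$b_slot[t]] * lv$b_w[t]
        if (f == 0) next
        src <- lv$b_src[[t]]
        ck <- paste(src, collapse = "*")
        y <- conv_cache[[ck]]
        if (is.null(y)) {
          y <- get_mid(src[1])
          for (s in src[-1]) y <- convolve_mid(y, get_mid(s))
          conv_cache[[ck]] <- y
        }
        B[lv$b_i[t], ] <- B[lv$b_i[t], ] - f * y
      }
    }
    dead <- which(abs(diag(A)) < 1e-12)
    if (length(dead))
      stop("EMU balance is singular: no flux reaches ",
           paste(lv$emus[dead], collapse = ", "), call. = FALSE)
    X <- tryCatch(solve(A, B), error = function(e)
      stop("EMU balance system of size ", lv$size,
           " is singular (disconnected zero-flux EMUs): ",
           conditionMessage(e), call. = FALSE))
    for (i in seq_len(n)) {
      x <- X[i, ]
      x[x < 0 & x > -1e-9] <- 0
      mids[[lv$emus[i]]] <- x / sum(x)
    }
  }
  out <- lapply(decomp$targets, get_mid)
  names(out) <- decomp$targets
  out
}

#' Default measured amino-acid fragment set
#'
#' Maps each measured intracellular free amino acid to the carbon skeleton
#' of its biosynthetic precursor(s): Ala from pyruvate, Gly and Ser from
#' the 3-phosphoglycerate branch, Asp from oxaloacetate, Glu from
#' alpha-ketoglutarate (as are Pro, and Thr from the aspartate skeleton),
#' His from ribose 5-phosphate, Phe and Tyr from two
#' PEP plus erythrose 4-phosphate (the shikimate route, PEP C1 of the
#' ring-bound PEP lost as CO2), Val from two pyruvate (C1 of one lost),
#' Leu from acetyl-CoA plus twice pyruvate C2-C3, and Ile from the
#' aspartate skeleton plus pyruvate C2-C3.  Amino acids built from several
#' precursor fragments are composite EMUs whose MID is the convolution of
#' the parts (`+`-separated in the `emu` key).  Override when the actual
#' GC-MS fragment list differs.
#'
#' @return data frame with columns `fragment`, `emu` (possibly composite
#'   EMU key) and `size` (total carbon count).
#' @export
default_fragments <- function() {
  df <- data.frame(
    fragment = c("Ala", "Gly", "Ser", "Asp", "Thr", "Glu", "Pro", "His",
                 "Phe", "Tyr", "Val", "Leu", "Ile"),
    emu = c("Pyr|1,2,3", "Gly|1,2", "Ser|1,2,3", "OAA|1,2,3,4",
            "OAA|1,2,3,4", "aKG|1,2,3,4,5", "aKG|1,2,3,4,5",
            "R5P|1,2,3,4,5",
            "PEP|1,2,3+PEP|2,3+E4P|1,2,3,4",
            "PEP|1,2,3+PEP|2,3+E4P|1,2,3,4",
            "Pyr|1,2,3+Pyr|2,3",
            "AcCoA|1,2+Pyr|2,3+Pyr|2,3",
            "OAA|1,2,3,4+Pyr|2,3"),
    stringsAsFactors = FALSE)
  df$size <- vapply(strsplit(df$emu, "+", fixed = TRUE),
                    function(p) sum(lengths(lapply(p, emu_atoms))), 1L)
  df
}

#' Simulate fragment MIDs, including composite (multi-precursor) fragments
#'
#' Composite fragment keys are `+`-separated EMU keys; their MID is the
#' convolution of the part MIDs (precursor pools label independently at
#' steady state).
#'
#' @inheritParams simulate_mids
#' @param frag_keys character vector of (possibly composite) EMU keys.
#' @return named list of MID vectors, one per requested key.
#' @export
simulate_fragments <- function(model, fluxmap, mixture, frag_keys,
                               decomp = NULL) {
  parts <- strsplit(unique(frag_keys), "+", fixed = TRUE)
  atomic <- unique(unlist(parts))
  if (is.null(decomp)) decomp <- emu_decompose(model, atomic)
  sim <- simulate_mids(model, fluxmap, mixture, targets = atomic,
                       decomp = decomp)
  out <- lapply(parts, function(p) {
    y <- sim[[p[1]]]
    for (s in p[-1]) y <- convolve_mid(y, sim[[s]])
    y
  })
  names(out) <- unique(frag_keys)
  out[frag_keys]
}

# ---- natural-abundance correction --------------------------------------

# mass-shift distributions of the non-carbon elements (terrestrial values)
element_shift_dist <- function(element) {
  switch(element,
    H = c(1 - 1.15e-4, 1.15e-4),
    N = c(1 - 3.64e-3, 3.64e-3),
    O = c(1 - 3.8e-4 - 2.05e-3, 3.8e-4, 2.05e-3),
    Si = c(1 - 4.685e-2 - 3.092e-2, 4.685e-2, 3.092e-2),
    S = c(1 - 7.5e-3 - 4.25e-2, 7.5e-3, 4.25e-2),
    stop("no isotope table for element ", element, call. = FALSE))
}

#' Correct a measured MID for natural isotope abundance of non-skeleton atoms
#'
#' GC-MS fragments carry H, N, O (and Si from derivatization) whose heavy
#' natural isotopes inflate the higher mass channels.  The correction builds
#' the mass-shift distribution of the non-carbon formula, forms the
#' lower-triangular convolution matrix M with `raw = M %*% clean`, and
#' solves for the clean carbon-skeleton MID.  Small negative entries
#' (within `-0.01`) are clipped to zero and the result renormalized; larger
#' negatives trigger a warning that the formula is inconsistent with the
#' data.
#'
#' @param raw measured MID vector (length = skeleton carbons + 1).
#' @param formula named integer vector of non-carbon atom counts, e.g.
#'   `c(H = 26, N = 1, O = 2, Si = 2)`.  An empty formula is the identity.
#' @return corrected MID vector, non-negative, summing to 1.
#' @export
correct_natural_abundance <- function(raw, formula = integer()) {
  if (any(raw < 0) || abs(sum(raw) - 1) > 1e-6)
    stop("raw MID must be non-negative and sum to 1", call. = FALSE)
  n <- length(raw)
  shift <- 1
  for (el in names(formula))
    for (i in seq_len(formula[[el]]))
      shift <- convolve_mid(shift, element_shift_dist(el))
  if (length(shift) == 1L) return(raw)
  M <- matrix(0, n, n)
  for (j in seq_len(n)) {
    k <- min(length(shift), n - j + 1L)
    M[j:(j + k - 1L), j] <- shift[seq_len(k)]
  }
  clean <- solve(M, raw)
  if (any(clean < -0.01))
    warning("natural-abundance correction produced entries < -0.01; ",
            "the non-carbon formula is likely inconsistent with the data")
  clean[clean < 0] <- 0
  clean / sum(clean)
}

# ---- MID table IO -------------------------------------------------------

#' Read / write MID measurement tables
#'
#' CSV dialect with columns `fragment`, `emu`, `replicate`, `M0 ... Mn`
#' (empty beyond the fragment's size) and `sd`.  The writer and reader
#' round-trip exactly at full double precision.
#'
#' @param x for the writer: a data frame as produced by [generate_mids()]
#'   (`$mids` element) with columns `fragment`, `emu`, `replicate`, `mass`,
#'   `value`, `sd`.
#' @param path file path.
#' @return `read_mids` returns the long-format data frame.
#' @export
write_mids <- function(x, path) {
  old <- options(digits = 17)
  on.exit(options(old))
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mids
#' @export
read_mids <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  num <- intersect(c("replicate", "mass", "value", "sd"), names(df))
  for (cn in num) df[[cn]] <- as.numeric(df[[cn]])
  df
}
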