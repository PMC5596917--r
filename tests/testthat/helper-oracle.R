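# Independent oracles used to validate the EMU engine and tracer code.
#
# The isotopomer oracle simulates the FULL positional isotopomer state of
# every balanced metabolite by fixed-point iteration of the isotopomer
# balance equations; it shares nothing with the EMU level-by-level linear
# solve beyond the parsed network.

# per-position 13C probabilities -> joint isotopomer distribution (2^n)
oracle_component_dist <- function(p) {
  # bit i-1 of the state index corresponds to carbon position i
  n <- length(p)
  d0 <- numeric(2^n)
  for (s in 0:(2^n - 1)) {
    pr <- 1
    for (i in seq_len(n)) {
      bit <- bitwAnd(bitwShiftR(s, i - 1L), 1L)
      pr <- pr * if (bit) p[i] else 1 - p[i]
    }
    d0[s + 1] <- pr
  }
  d0
}

oracle_input_dist <- function(mixture, n) {
  d <- numeric(2^n)
  for (nm in names(mixture$fractions))
    d <- d + mixture$fractions[[nm]] *
      oracle_component_dist(mixture$patterns[[nm]][seq_len(n)])
  d
}

# full isotopomer steady state by damped fixed-point iteration
oracle_isotopomers <- function(model, fluxmap, mixture,
                               tol = 1e-13, maxit = 20000) {
  role <- setNames(model$metabolites$role, model$metabolites$id)
  nc <- model$carbons
  variants <- riboflux:::network_variants(model)
  dirflux <- function(rxn, dir) {
    v <- fluxmap$net[[rxn]]
    e <- if (rxn %in% names(fluxmap$exch)) fluxmap$exch[[rxn]] else 0
    if (dir > 0) e + max(v, 0) else e + max(-v, 0)
  }
  bal <- model$metabolites$id[model$metabolites$role == "balanced"]
  state <- list()
  for (m in bal) state[[m]] <- rep(1 / 2^nc[m], 2^nc[m])
  for (m in model$metabolites$id[role == "substrate"])
    state[[m]] <- oracle_input_dist(mixture, nc[m])

  cons <- setNames(numeric(length(bal)), bal)
  for (r in model$reactions) {
    if (r$drain) {
      for (k in seq_len(nrow(r$sub)))
        if (r$sub$id[k] %in% bal)
          cons[r$sub$id[k]] <- cons[r$sub$id[k]] +
            r$sub$coef[k] * fluxmap$net[[r$id]]
      next
    }
    for (m in r$sub_inst) if (m %in% bal)
      cons[m] <- cons[m] + dirflux(r$id, 1)
    if (r$reversible)
      for (m in r$prod_inst) if (m %in% bal)
        cons[m] <- cons[m] + dirflux(r$id, -1)
  }

  for (it in seq_len(maxit)) {
    prod_acc <- list()
    for (m in bal) prod_acc[[m]] <- numeric(2^nc[m])
    for (v in variants) {
      f <- dirflux(v$rxn, v$dir) * v$weight
      if (f == 0) next
      subs <- v$subs
      dims <- 2^nc[subs]
      n_sub <- length(subs)
      # enumerate the joint substrate isotopomer states
      joint_states <- expand.grid(lapply(dims, function(d) 0:(d - 1)))
      pr <- rep(1, nrow(joint_states))
      for (si in seq_len(n_sub))
        pr <- pr * state[[subs[si]]][joint_states[[si]] + 1]
      for (pi in seq_along(v$prods)) {
        pm <- v$prods[pi]
        if (!pm %in% bal) next
        a <- v$assign[[pi]]
        # product state bits from substrate state bits
        pstate <- integer(nrow(joint_states))
        for (q in seq_len(nrow(a))) {
          sbit <- bitwAnd(bitwShiftR(joint_states[[a[q, "sub"]]],
                                     a[q, "pos"] - 1L), 1L)
          pstate <- pstate + sbit * 2L^(q - 1L)
        }
        acc <- prod_acc[[pm]]
        for (k in seq_along(pstate))
          acc[pstate[k] + 1] <- acc[pstate[k] + 1] + f * pr[k]
        prod_acc[[pm]] <- acc
      }
    }
    delta <- 0
    for (m in bal) {
      new <- prod_acc[[m]] / cons[[m]]
      delta <- max(delta, max(abs(new - state[[m]])))
      state[[m]] <- new
    }
    if (delta < tol) break
  }
  if (delta >= tol) stop("isotopomer oracle did not converge")
  state
}

# MID of an EMU from a full isotopomer distribution
oracle_emu_mid <- function(state_vec, n_carbons, atoms) {
  mid <- numeric(length(atoms) + 1)
  for (s in 0:(2^n_carbons - 1)) {
    w <- 0
    for (a in atoms) w <- w + bitwAnd(bitwShiftR(s, a - 1L), 1L)
    mid[w + 1] <- mid[w + 1] + state_vec[s + 1]
  }
  mid
}

oracle_mid <- function(model, fluxmap, mixture, emu_key) {
  m <- sub("\\|.*$", "", emu_key)
  atoms <- as.integer(strsplit(sub("^.*\\|", "", emu_key), ",")[[1]])
  st <- oracle_isotopomers(model, fluxmap, mixture)
  oracle_emu_mid(st[[m]], model$carbons[[m]], atoms)
}
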