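#' @importFrom stats setNames
NULL

# ---- equation / atom-map parsing ---------------------------------------

# "3 Ru5P + R5P -> Rib + 3 CO2" -> list(sub = data.frame(id, coef), prod = ...)
parse_equation <- function(eq) {
  arrow <- if (grepl("<->", eq, fixed = TRUE)) "<->" else "->"
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(sides) != 2L)
    stop("malformed reaction equation: ", eq, call. = FALSE)
  parse_side <- function(s) {
    s <- trimws(s)
    if (s == "" || s == ".")
      return(data.frame(id = character(), coef = numeric(),
                        stringsAsFactors = FALSE))
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    coef <- rep(1, length(terms))
    id <- terms
    has_coef <- grepl("^[0-9.]+\\s+", terms)
    coef[has_coef] <- as.numeric(sub("\\s.*$", "", terms[has_coef]))
    id[has_coef] <- sub("^[0-9.]+\\s+", "", terms[has_coef])
    data.frame(id = id, coef = coef, stringsAsFactors = FALSE)
  }
  list(sub = parse_side(sides[1]), prod = parse_side(sides[2]),
       reversible = arrow == "<->")
}

# Expand a side into one entry per molecule instance ("3 Ru5P" -> 3 copies).
expand_instances <- function(side, where) {
  if (nrow(side) == 0L) return(character())
  if (any(abs(side$coef - round(side$coef)) > 1e-12))
    stop("non-integer stoichiometry needs drain = TRUE (", where, ")",
         call. = FALSE)
  rep(side$id, times = round(side$coef))
}

# Parse one atom-map string "abcde + fghij : abfghij + cde" against the
# instance-expanded substrate/product lists.  Returns, per product instance,
# a 2-column matrix (substrate instance index, substrate carbon position).
parse_atom_map <- function(map, sub_inst, prod_inst, carbons, rxn_id) {
  sides <- strsplit(map, ":", fixed = TRUE)[[1]]
  if (length(sides) != 2L)
    stop("malformed atom map in reaction '", rxn_id, "': ", map,
         call. = FALSE)
  split_groups <- function(s) trimws(strsplit(s, "+", fixed = TRUE)[[1]])
  sg <- split_groups(sides[1])
  pg <- split_groups(sides[2])
  if (length(sg) != length(sub_inst) || length(pg) != length(prod_inst))
    stop("atom map group count does not match molecule instances in '",
         rxn_id, "'", call. = FALSE)
  sub_letters <- character()
  sub_where <- list()
  for (i in seq_along(sg)) {
    letters_i <- strsplit(sg[i], "")[[1]]
    nc <- carbons[[sub_inst[i]]]
    if (length(letters_i) != nc)
      stop("atom map in '", rxn_id, "': substrate ", sub_inst[i],
           " has ", nc, " carbons but map gives ", length(letters_i),
           call. = FALSE)
    sub_letters <- c(sub_letters, letters_i)
    sub_where <- c(sub_where,
                   lapply(seq_len(nc), function(p) c(i, p)))
  }
  if (anyDuplicated(sub_letters))
    stop("atom map in '", rxn_id, "': duplicated substrate atom letter",
         call. = FALSE)
  names(sub_where) <- sub_letters
  prod_letters <- unlist(strsplit(pg, ""))
  if (length(prod_letters) != length(sub_letters) ||
      !setequal(prod_letters, sub_letters) || anyDuplicated(prod_letters))
    stop("atom map in '", rxn_id,
         "' is not a bijection on carbon positions", call. = FALSE)
  assign <- vector("list", length(pg))
  for (j in seq_along(pg)) {
    letters_j <- strsplit(pg[j], "")[[1]]
    nc <- carbons[[prod_inst[j]]]
    if (length(letters_j) != nc)
      stop("atom map in '", rxn_id, "': product ", prod_inst[j],
           " has ", nc, " carbons but map gives ", length(letters_j),
           call. = FALSE)
    assign[[j]] <- do.call(rbind, sub_where[letters_j])
    colnames(assign[[j]]) <- c("sub", "pos")
  }
  assign
}

# Serialize an assign structure back to letter notation (used by the file
# writer and by round-trip tests of atom-map inversion).
format_atom_map <- function(assign, sub_inst, carbons) {
  n_each <- vapply(sub_inst, function(m) carbons[[m]], 1L)
  total <- sum(n_each)
  pool <- c(letters, LETTERS)[seq_len(total)]
  offs <- cumsum(c(0L, n_each))
  sub_groups <- lapply(seq_along(sub_inst),
                       function(i) pool[(offs[i] + 1L):offs[i + 1L]])
  prod_groups <- vapply(assign, function(a) {
    paste(vapply(seq_len(nrow(a)),
                 function(k) sub_groups[[a[k, "sub"]]][a[k, "pos"]], ""),
          collapse = "")
  }, "")
  paste(paste(vapply(sub_groups, paste, "", collapse = ""), collapse = " + "),
        ":", paste(prod_groups, collapse = " + "))
}

#' Define a reaction with carbon atom transitions
#'
#' Builds one reaction of a carbon-atom-resolved metabolic network.  Atom
#' transitions use the conventional letter notation: each substrate carbon is
#' assigned a letter, and the product side lists how those letters are
#' redistributed, e.g. `"abcdef : bcdef + a"` for a decarboxylation.
#' Molecules with rotational symmetry (succinate, fumarate) are handled by
#' supplying several equally weighted alternative maps.
#'
#' @param id reaction name.
#' @param equation reaction string, e.g. `"Xu5P + E4P <-> F6P + GAP"`.
#'   `"<->"` marks the reaction reversible.  Integer stoichiometric
#'   coefficients expand into molecule instances that the atom map addresses
#'   one by one.
#' @param atom_map character vector of atom-transition strings; more than one
#'   entry means equally weighted scrambling alternatives.  May be `NULL`
#'   only for `drain = TRUE` reactions.
#' @param pathway pathway tag used for cofactor grouping (`"EMP"`, `"PP"`,
#'   `"TCA"`, `"overflow"`, `"anaplerosis"`, `"biosynthesis"`,
#'   `"transport"`, `"other"`).
#' @param cofactors named numeric vector of cofactor coefficients per unit
#'   flux; recognised names are `NADH`, `NADPH`, `FADH2`, `ATP`, `CO2`, `O2`.
#' @param drain logical; drain reactions (biomass) carry fractional
#'   coefficients, no atom map, and export carbon out of the labeled network.
#' @return an object of class `flux_reaction`.
#' @export
flux_reaction <- function(id, equation, atom_map = NULL, pathway = "other",
                          cofactors = numeric(), drain = FALSE) {
  eq <- parse_equation(equation)
  r <- list(id = id, equation = equation, sub = eq$sub, prod = eq$prod,
            reversible = eq$reversible, pathway = pathway,
            cofactors = cofactors, drain = drain, atom_map = atom_map)
  class(r) <- "flux_reaction"
  r
}

#' @export
print.flux_reaction <- function(x, ...) {
  cat(sprintf("%-8s %s%s [%s]\n", x$id, x$equation,
              if (x$drain) " (drain)" else "", x$pathway))
  invisible(x)
}

# ---- network assembly ---------------------------------------------------

#' Assemble a carbon-labeled metabolic network
#'
#' @param metabolites data frame with columns `id`, `carbons`, `role`
#'   (`"balanced"`, `"substrate"` or `"sink"`).
#' @param reactions list of [flux_reaction()] objects.
#' @return object of class `flux_network` with parsed, validated atom maps.
#' @export
flux_network <- function(metabolites, reactions) {
  stopifnot(all(c("id", "carbons", "role") %in% names(metabolites)))
  if (anyDuplicated(metabolites$id))
    stop("duplicated metabolite ids", call. = FALSE)
  carbons <- setNames(as.integer(metabolites$carbons), metabolites$id)
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  for (nm in names(reactions)) {
    r <- reactions[[nm]]
    unknown <- setdiff(c(r$sub$id, r$prod$id), metabolites$id)
    if (length(unknown))
      stop("reaction '", nm, "' references unknown metabolite(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    if (!r$drain) {
      r$sub_inst <- expand_instances(r$sub, nm)
      r$prod_inst <- expand_instances(r$prod, nm)
      if (is.null(r$atom_map))
        stop("reaction '", nm, "' needs an atom map (or drain = TRUE)",
             call. = FALSE)
      r$maps <- lapply(r$atom_map, parse_atom_map,
                       sub_inst = r$sub_inst, prod_inst = r$prod_inst,
                       carbons = carbons, rxn_id = nm)
      r$map_weight <- rep(1 / length(r$maps), length(r$maps))
    }
    reactions[[nm]] <- r
  }
  net <- list(metabolites = metabolites, reactions = reactions,
              carbons = carbons)
  class(net) <- "flux_network"
  net
}

#' @export
print.flux_network <- function(x, ...) {
  nb <- sum(x$metabolites$role == "balanced")
  cat("Carbon-labeled metabolic network\n")
  cat("  metabolites:", nrow(x$metabolites),
      sprintf("(%d balanced)", nb), "\n")
  cat("  reactions:  ", length(x$reactions),
      sprintf("(%d reversible)",
              sum(vapply(x$reactions, `[[`, TRUE, "reversible"))), "\n")
  S <- stoichiometric_matrix(x)
  cat("  steady-state degrees of freedom:", ncol(S) - qr(S)$rank, "\n")
  invisible(x)
}

#' Biomass precursor demand of the default network
#'
#' Precursor drain coefficients (mmol precursor per gDCW) for growth of
#' *B. subtilis*, scaled so that total biomass carbon equals
#' `biomass_carbon` mmolC/gDCW.  The default 40.9 mmolC/gDCW corresponds to a
#' biomass carbon content of ~0.49 gC/gDCW, consistent with the measured
#' biomass carbon output of the batches when multiplied by the growth rate.
#'
#' @param biomass_carbon total biomass carbon, mmolC per gDCW.
#' @return named numeric vector of precursor coefficients.
#' @export
biomass_demand <- function(biomass_carbon = 40.9) {
  base <- c(G6P = 0.205, F6P = 0.071, R5P = 0.898, E4P = 0.361,
            GAP = 0.129, PGA = 0.45, Ser = 0.40, Gly = 0.60,
            PEP = 0.519, Pyr = 2.833, AcCoA = 3.748, OAA = 1.787,
            aKG = 1.079)
  ncarb <- c(G6P = 6, F6P = 6, R5P = 5, E4P = 4, GAP = 3, PGA = 3,
             Ser = 3, Gly = 2, PEP = 3, Pyr = 3, AcCoA = 2, OAA = 4,
             aKG = 5)
  base * biomass_carbon / sum(base * ncarb)
}

#' Build the default B. subtilis central-carbon network
#'
#' Encodes the carbon-atom-resolved network used throughout the package:
#' glucose uptake into glycolysis (EMP), the oxidative and non-oxidative
#' pentose phosphate pathway (PP) with a lumped riboflavin drain from
#' Ru5P/R5P, the serine/glycine branch, pyruvate overflow to lactate and
#' acetate (optionally acetoin), the full TCA cycle with succinate/fumarate
#' symmetry scrambling, pyruvate-carboxylase anaplerosis, an intracellular
#' CO2 pool, and a biomass drain over eleven precursors.  Atom transitions
#' are the canonical textbook mappings; the two CO2 released in the first
#' TCA turn derive from the oxaloacetate carboxyl carbons.
#'
#' @param include_acetoin add the acetoin overflow reaction
#'   (2 Pyr -> acetoin + 2 CO2); excluded by default.
#' @param biomass_carbon biomass carbon content passed to
#'   [biomass_demand()].
#' @return a validated `flux_network`.
#' @export
build_default_network <- function(include_acetoin = FALSE,
                                  biomass_carbon = 40.9) {
  mets <- data.frame(
    id = c("Glc_ext", "G6P", "F6P", "FBP", "GAP", "PGA", "PEP", "Pyr",
           "6PG", "Ru5P", "Xu5P", "R5P", "S7P", "E4P",
           "Ser", "Gly", "C1",
           "AcCoA", "Cit", "aKG", "Suc", "Fum", "Mal", "OAA",
           "CO2", "CO2_ext", "Lac", "Ac", "Actn", "Rib"),
    carbons = c(6, 6, 6, 6, 3, 3, 3, 3,
                6, 5, 5, 5, 7, 4,
                3, 2, 1,
                2, 6, 5, 4, 4, 4, 4,
                1, 1, 3, 2, 4, 17),
    role = c("substrate", rep("balanced", 7),
             rep("balanced", 6),
             "balanced", "balanced", "sink",
             rep("balanced", 7),
             "balanced", "sink", "sink", "sink", "sink", "sink"),
    stringsAsFactors = FALSE)

  bm <- biomass_demand(biomass_carbon)
  bm_eq <- paste(paste(sprintf("%.6f %s", bm, names(bm)), collapse = " + "),
                 "-> .")

  rxns <- list(
    flux_reaction("upt", "Glc_ext -> G6P", "abcdef : abcdef",
                  pathway = "transport", cofactors = c(ATP = -1)),
    flux_reaction("pgi", "G6P <-> F6P", "abcdef : abcdef", pathway = "EMP"),
    flux_reaction("pfk", "F6P -> FBP", "abcdef : abcdef",
                  pathway = "EMP", cofactors = c(ATP = -1)),
    flux_reaction("fba", "FBP -> GAP + GAP", "abcdef : cba + def",
                  pathway = "EMP"),
    flux_reaction("gapdh", "GAP -> PGA", "abc : abc",
                  pathway = "EMP", cofactors = c(NADH = 1, ATP = 1)),
    flux_reaction("eno", "PGA -> PEP", "abc : abc", pathway = "EMP"),
    flux_reaction("pyk", "PEP -> Pyr", "abc : abc",
                  pathway = "EMP", cofactors = c(ATP = 1)),
    flux_reaction("zwf", "G6P -> 6PG", "abcdef : abcdef",
                  pathway = "PP", cofactors = c(NADPH = 1)),
    flux_reaction("gnd", "6PG -> Ru5P + CO2", "abcdef : bcdef + a",
                  pathway = "PP", cofactors = c(NADPH = 1, CO2 = 1)),
    flux_reaction("rpe", "Ru5P <-> Xu5P", "abcde : abcde", pathway = "PP"),
    flux_reaction("rpi", "Ru5P <-> R5P", "abcde : abcde", pathway = "PP"),
    flux_reaction("tkt1", "Xu5P + R5P <-> S7P + GAP",
                  "abcde + fghij : abfghij + cde", pathway = "PP"),
    flux_reaction("tal", "S7P + GAP <-> F6P + E4P",
                  "abcdefg + hij : abchij + defg", pathway = "PP"),
    flux_reaction("tkt2", "Xu5P + E4P <-> F6P + GAP",
                  "abcde + fghi : abfghi + cde", pathway = "PP"),
    flux_reaction("ser_syn", "PGA -> Ser", "abc : abc",
                  pathway = "biosynthesis", cofactors = c(NADH = 1)),
    flux_reaction("shmt", "Ser -> Gly + C1", "abc : ab + c",
                  pathway = "biosynthesis"),
    flux_reaction("pdh", "Pyr -> AcCoA + CO2", "abc : bc + a",
                  pathway = "other", cofactors = c(NADH = 1, CO2 = 1)),
    flux_reaction("ldh", "Pyr -> Lac", "abc : abc",
                  pathway = "overflow", cofactors = c(NADH = -1)),
    flux_reaction("ack", "AcCoA -> Ac", "ab : ab",
                  pathway = "overflow", cofactors = c(ATP = 1)),
    flux_reaction("cs", "AcCoA + OAA -> Cit", "ab + cdef : fedbac",
                  pathway = "TCA"),
    flux_reaction("icdh", "Cit -> aKG + CO2", "abcdef : abcde + f",
                  pathway = "TCA", cofactors = c(NADPH = 1, CO2 = 1)),
    flux_reaction("akgdh", "aKG -> Suc + CO2", "abcde : bcde + a",
                  pathway = "TCA",
                  cofactors = c(NADH = 1, ATP = 1, CO2 = 1)),
    flux_reaction("sdh", "Suc <-> Fum",
                  c("abcd : abcd", "abcd : dcba"),
                  pathway = "TCA", cofactors = c(FADH2 = 1)),
    flux_reaction("fum", "Fum <-> Mal",
                  c("abcd : abcd", "abcd : dcba"),
                  pathway = "TCA"),
    flux_reaction("mdh", "Mal <-> OAA", "abcd : abcd",
                  pathway = "TCA", cofactors = c(NADH = 1)),
    flux_reaction("pyc", "Pyr + CO2 -> OAA", "abc + d : abcd",
                  pathway = "anaplerosis",
                  cofactors = c(ATP = -1, CO2 = -1)),
    flux_reaction("rib_syn", "3 Ru5P + R5P -> Rib + 3 CO2",
                  "abcde + fghij + klmno + pqrst : bcdeghijlmnopqrst + a + f + k",
                  pathway = "biosynthesis", cofactors = c(CO2 = 3)),
    flux_reaction("co2_ex", "CO2 -> CO2_ext", "a : a",
                  pathway = "transport"),
    flux_reaction("biomass", bm_eq, pathway = "biosynthesis", drain = TRUE)
  )
  if (include_acetoin)
    rxns <- c(rxns, list(
      flux_reaction("als", "Pyr + Pyr -> Actn + CO2 + CO2",
                    "abc + def : bcef + a + d",
                    pathway = "overflow", cofactors = c(CO2 = 2))))
  flux_network(mets, rxns)
}

# ---- validation ---------------------------------------------------------

#' Validate a carbon-labeled network
#'
#' Checks every reaction for carbon conservation (substrate carbons equal
#' product carbons, CO2 being an explicit product), atom-map bijectivity,
#' and the network for orphan balanced metabolites (never produced or never
#' consumed).  Drain reactions are exempt from atom-map checks.
#'
#' @param model a `flux_network`.
#' @return a list with character vectors `violations` (errors) and
#'   `warnings`; both empty for a well-formed network.
#' @export
validate_network <- function(model) {
  violations <- character()
  warns <- character()
  for (r in model$reactions) {
    if (r$drain) next
    cs <- sum(model$carbons[r$sub_inst])
    cp <- sum(model$carbons[r$prod_inst])
    if (cs != cp)
      violations <- c(violations, sprintf(
        "reaction '%s': %d substrate carbons but %d product carbons",
        r$id, cs, cp))
    for (m in r$maps) {
      mapped <- do.call(rbind, m)
      key <- paste(mapped[, "sub"], mapped[, "pos"])
      if (anyDuplicated(key) || nrow(mapped) != cs)
        violations <- c(violations, sprintf(
          "reaction '%s': atom map is not a bijection", r$id))
    }
  }
  consumed <- produced <- character()
  for (r in model$reactions) {
    subs <- r$sub$id; prods <- r$prod$id
    consumed <- c(consumed, subs, if (r$reversible) prods)
    produced <- c(produced, prods, if (r$reversible) subs)
  }
  bal <- model$metabolites$id[model$metabolites$role == "balanced"]
  for (m in bal) {
    if (!m %in% produced)
      warns <- c(warns, sprintf("balanced metabolite '%s' is never produced", m))
    if (!m %in% consumed)
      warns <- c(warns, sprintf("balanced metabolite '%s' is never consumed", m))
  }
  list(violations = violations, warnings = warns)
}

# ---- stoichiometry ------------------------------------------------------

#' Stoichiometric matrix over balanced metabolites
#'
#' @param model a `flux_network`.
#' @return matrix S (balanced metabolites x reactions) of signed net
#'   coefficients; steady state is `S %*% v == 0`.
#' @export
stoichiometric_matrix <- function(model) {
  bal <- model$metabolites$id[model$metabolites$role == "balanced"]
  S <- matrix(0, nrow = length(bal), ncol = length(model$reactions),
              dimnames = list(bal, names(model$reactions)))
  for (j in seq_along(model$reactions)) {
    r <- model$reactions[[j]]
    for (k in seq_len(nrow(r$sub)))
      if (r$sub$id[k] %in% bal)
        S[r$sub$id[k], j] <- S[r$sub$id[k], j] - r$sub$coef[k]
    for (k in seq_len(nrow(r$prod)))
      if (r$prod$id[k] %in% bal)
        S[r$prod$id[k], j] <- S[r$prod$id[k], j] + r$prod$coef[k]
  }
  S
}

# Orthonormal null-space basis of S (free-flux directions), deterministic.
null_space <- function(S, tol = 1e-10) {
  sv <- svd(S, nu = 0, nv = ncol(S))
  d <- c(sv$d, rep(0, ncol(S) - length(sv$d)))
  keep <- d < tol * max(d, 1)
  N <- sv$v[, keep, drop = FALSE]
  # fix signs for determinism
  for (j in seq_len(ncol(N))) {
    i <- which.max(abs(N[, j]))
    if (N[i, j] < 0) N[, j] <- -N[, j]
  }
  rownames(N) <- colnames(S)
  N
}

# ---- directed reaction variants (internal, shared by EMU + simulation) --

# Each variant is one unidirectional, scrambling-resolved elementary flow:
# list(rxn, dir (+1 fwd / -1 bwd), weight, subs, prods, assign).
network_variants <- function(model) {
  out <- list()
  for (r in model$reactions) {
    if (r$drain) next
    for (k in seq_along(r$maps)) {
      out[[length(out) + 1L]] <- list(
        rxn = r$id, dir = 1L, weight = r$map_weight[k],
        subs = r$sub_inst, prods = r$prod_inst, assign = r$maps[[k]])
    }
    if (r$reversible) {
      for (k in seq_along(r$maps)) {
        # invert the bijection: former products become substrates
        fwd <- r$maps[[k]]
        inv <- vector("list", length(r$sub_inst))
        for (si in seq_along(r$sub_inst))
          inv[[si]] <- matrix(0L, nrow = model$carbons[r$sub_inst[si]],
                              ncol = 2,
                              dimnames = list(NULL, c("sub", "pos")))
        for (pi in seq_along(fwd)) {
          a <- fwd[[pi]]
          for (q in seq_len(nrow(a)))
            inv[[a[q, "sub"]]][a[q, "pos"], ] <- c(pi, q)
        }
        out[[length(out) + 1L]] <- list(
          rxn = r$id, dir = -1L, weight = r$map_weight[k],
          subs = r$prod_inst, prods = r$sub_inst, assign = inv)
      }
    }
  }
  out
}

# ---- file round trip ----------------------------------------------------

#' Read / write a network definition file
#'
#' The on-disk format is JSON with a `metabolites` table and a `reactions`
#' list carrying (id, equation, atom_map, pathway, cofactors, drain); atom
#' maps are re-parsed (and bijectivity re-checked) at load time, so the
#' round trip is exact.
#'
#' @param path file path.
#' @return `read_network` returns a `flux_network`.
#' @export
read_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  rxns <- lapply(seq_len(nrow(obj$reactions)), function(i) {
    row <- obj$reactions[i, ]
    cof <- obj$cofactors[[i]]
    flux_reaction(row$id, row$equation,
                  atom_map = if (row$drain) NULL else obj$atom_maps[[i]],
                  pathway = row$pathway,
                  cofactors = if (length(cof)) unlist(cof) else numeric(),
                  drain = row$drain)
  })
  flux_network(obj$metabolites, rxns)
}

#' @param model a `flux_network`.
#' @rdname read_network
#' @export
write_network <- function(model, path) {
  rx <- model$reactions
  obj <- list(
    metabolites = model$metabolites,
    reactions = data.frame(
      id = vapply(rx, `[[`, "", "id"),
      equation = vapply(rx, `[[`, "", "equation"),
      pathway = vapply(rx, `[[`, "", "pathway"),
      drain = vapply(rx, `[[`, TRUE, "drain"),
      stringsAsFactors = FALSE),
    atom_maps = lapply(rx, function(r) if (r$drain) character() else r$atom_map),
    cofactors = lapply(rx, function(r) as.list(r$cofactors))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
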