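---
title: "Quantifying central-carbon fluxes in riboflavin-producing B. subtilis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying central-carbon fluxes in riboflavin-producing B. subtilis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboflux)
```

## The scientific problem

Industrial riboflavin fermentations with *Bacillus subtilis* lose
productivity sharply when dissolved-oxygen (DO) tension drops. The
mechanistic question is where the carbon goes: riboflavin is drawn from
ribulose 5-phosphate and GTP, both products of the pentose phosphate (PP)
pathway, so the split of glucose-6-phosphate between the oxidative PP
pathway and glycolysis (EMP), together with TCA-cycle activity and
overflow metabolism, determines both growth and product formation.
¹³C metabolic flux analysis (¹³C-MFA) resolves those intracellular splits
by growing cells on a defined ¹³C-glucose mixture, measuring the mass
isotopomer distributions (MIDs) of intracellular free amino acids by
GC-MS, and finding the flux map whose simulated labeling best explains
the measurements.

This package implements that pipeline end to end: the carbon-atom-resolved
network, EMU-based forward simulation of MIDs, weighted least-squares flux
estimation with a χ² model test and profile confidence intervals, cofactor
and ATP balancing, batch-kinetics and carbon-recovery bookkeeping, and a
synthetic-data generator that makes every stage testable without access to
the original raw measurements.

## The metabolic model

`build_default_network()` encodes a single-compartment model of
*B. subtilis* central carbon metabolism: glucose uptake into G6P, EMP
glycolysis, oxidative PP (G6P → 6PG → Ru5P + CO2) and the non-oxidative
rearrangements (transketolase moving C1–C2 units, transaldolase C1–C3
units), the serine/glycine branch with a C1 (one-carbon) drain, pyruvate
overflow to lactate and acetate (optionally acetoin), the full TCA cycle,
pyruvate-carboxylase anaplerosis, an intracellular CO2 pool with an export
reaction, a lumped riboflavin drain, and a biomass drain over eleven
precursors. Being a prokaryote with one pool per metabolite in the flux
map, a single cytosolic compartment is the appropriate resolution; the
format retains room for compartment flags for reuse with other organisms.

Atom transitions are the canonical textbook mappings; they are written in
letter notation (`"abcdef : bcdef + a"`) and validated as bijections at
parse time. Two conventions deserve note:

* **Molecular symmetry.** Succinate and fumarate are symmetric; the
  succinate-dehydrogenase and fumarase steps each carry two equally
  weighted mirror-image atom maps, which is equivalent to 50:50 scrambling
  at those nodes.
* **TCA decarboxylations.** Both CO2 molecules released in the first turn
  (isocitrate dehydrogenase, α-ketoglutarate dehydrogenase) derive from
  the oxaloacetate carboxyl carbons, per the classic citrate-synthase
  stereochemistry.

Two lumped reactions are deliberate simplifications. Riboflavin synthesis
is encoded as `3 Ru5P + R5P -> Rib(17C) + 3 CO2`: carbon-conserving and
with the correct pentose demand per riboflavin, but not the literal
multi-step GTP + DHBP chemistry. Because riboflavin is a sink whose MID is
never measured or simulated, only its carbon stoichiometry matters.
Similarly, glucose uptake is written hexokinase-style (ATP −1) rather
than as the PTS reaction; this matches the substrate-level-phosphorylation
accounting convention used for the ATP summaries (see below).

Biomass precursor coefficients follow the standard Gram-positive demand
table, rescaled so total biomass carbon is 40.9 mmolC/gDCW
(`biomass_demand()`). That constant is chosen so that biomass carbon
output equals growth rate × biomass carbon content, which reproduces the
measured biomass carbon rates of both batches (e.g. 40.9 × 0.092 ≈ 3.77
mmolC/gDCW/h) — i.e. the model's carbon bookkeeping is consistent with
the fermentation data it will be fitted against.

## Tracer and EMU simulation

The labeling experiments use a glucose mixture of 30% natural-abundance
glucose, 20% [1-¹³C]-glucose and 50% [U-¹³C]-glucose
(`tracer_mixture()`). Natural ¹³C abundance defaults to 0.0107 per
position, the standard terrestrial value. The [1-¹³C] component is
position-1 pure; custom per-position patterns can be supplied.

`simulate_mids()` uses the elementary metabolite unit (EMU)
decomposition: starting from the measured fragments it traces backwards
through every producing reaction to the minimal closed set of carbon
subsets whose balances determine the targets, then solves one linear
system per EMU size, smallest first. Condensation reactions appear as
convolutions of smaller EMUs, so each level depends only on levels below
it, and each linear system is small (under a hundred EMUs per level for
this network); dense LU is used throughout. The decomposition is compiled
once and reused across the thousands of simulations an optimization run
needs (about 3 ms per simulation for the full network).

The engine is validated against an independent oracle that enumerates the
full positional-isotopomer state (up to 2¹⁰ states) and solves the
balance by fixed-point iteration; on a suite of toy networks covering
cleavage, condensation, reversible exchange and symmetric scrambling the
two agree to 10⁻⁸. Three structural properties are also enforced by
tests: MIDs sum to one, are invariant to rescaling all fluxes by a
positive constant, and reduce exactly to the irreversible solution when
an exchange flux is set to zero.

Measured amino acids map to precursor carbon skeletons: Ala ← pyruvate,
Ser/Gly ← the 3-phosphoglycerate branch, Asp/Thr ← oxaloacetate, Glu/Pro
← α-ketoglutarate, His ← ribose 5-phosphate, Phe/Tyr ← 2 PEP + E4P
(shikimate route), Val ← 2 pyruvate, Leu ← acetyl-CoA + 2 pyruvate
C2–C3, Ile ← the aspartate skeleton + pyruvate C2–C3. Fragments built
from several precursors are simulated as convolutions of the part EMUs
(pools label independently at steady state). The set is configurable
(`default_fragments()`) because the exact GC-MS fragment list of any
given study varies; the default is the panel of free amino acids such
studies routinely quantify.

GC-MS fragments also carry H, N, O and derivatization Si whose heavy
isotopes inflate high mass channels; `correct_natural_abundance()`
performs the standard matrix correction (forward convolution matrix of
the non-carbon formula, solved back and renormalized).

## Flux estimation

`fit_fluxes()` estimates the flux map by minimizing the variance-weighted
squared deviation between simulated and measured fragment MIDs plus
external rate constraints (glucose uptake, growth rate, riboflavin
production; optionally CO2 evolution and secretion rates). Net fluxes are
parameterized in an orthonormal null-space basis of the stoichiometric
matrix (steady state holds by construction, 6 free directions for the
default network); exchange fluxes of reversible reactions live on the
bounded coordinate ρ = x/(1+x) ∈ [0, 0.9] for optimizer stability.
Irreversible reactions are kept non-negative by a heavy penalty residual,
which is zero on the feasible set.

**Whitened residuals.** A normalized MID vector sums to one, so its
additive measurement noise has the singular covariance
σ²(I − x1ᵀ)(I − 1xᵀ). Residuals are whitened per measurement vector into
the (m−1)-dimensional sum-zero subspace. This has two consequences worth
making explicit: the degrees of freedom bookkeeping (n−1 independent
values per MID vector of length n, one per rate constraint) becomes
exact rather than approximate, and the estimator uses the correct
weighting. Monte-Carlo checks confirm the whitened SSR at the true fluxes
matches its nominal χ² expectation to within the small bias introduced by
clipping negative noise draws at zero.

**Optimization.** Levenberg–Marquardt (`minpack.lm::nls.lm`) with
multiple starts: a pool of feasible random flux maps (plus a
deterministic grid over the PP and TCA splits) is screened by objective
value, the best few are refined in two stages (net fluxes first with
exchanges held, then everything), and the search stops early once at
least three refined starts have converged and the best SSR falls below
the median of the χ² null — a statistically perfect fit that further
restarts cannot improve upon in any decision-relevant way. Defaults are
20 restarts and an SSR tolerance of 10⁻⁹.

**Model test and dof.** The fit is accepted when the minimal SSR falls
below the χ² quantile at 95% for the residual degrees of freedom
(`chi2_accept()`). The parameter count subtracted is the *rank of the
measurement Jacobian at the optimum*, not the raw parameter count:
structurally flat directions — for example the succinate-dehydrogenase
exchange, which is invisible to labeling because fumarate scrambling
already symmetrizes the pool — cannot consume a degree of freedom. The
fit warns about such non-identifiable directions.

**Confidence intervals.** `confidence_intervals()` (also available as
`confint()`) profiles the SSR: the flux of interest is pinned at trial
values while all other parameters are re-optimized, and the interval
collects values with profiled SSR within the χ²₁ quantile of the level
above the minimum. The boundary is located by doubling expansion and
bisection (to 10⁻³ of the local flux scale); a side that never crosses
the threshold inside the search window is reported open-ended rather than
raising an error, which is the honest answer for structurally
non-identifiable fluxes. Coverage was verified to meet the nominal 95%
rate (the profiles run slightly conservative) on a reduced split/rejoin
problem over 100 replicates.

## Energy and redox accounting

`cofactor_rates()` sums cofactor coefficients × net flux, grouped by
pathway tag. NADH arises in glycolysis (GAPDH), the TCA cycle (α-KG
dehydrogenase, malate dehydrogenase) and pyruvate dehydrogenase (tagged
separately from the cycle proper); NADPH arises in the oxidative PP
pathway and at isocitrate dehydrogenase (NADP-dependent in
*B. subtilis*); FADH₂ from succinate dehydrogenase is tracked separately
and **not** converted to ATP. Substrate-level ATP nets the kinase gains
(phosphoglycerate kinase, pyruvate kinase, succinyl-CoA synthetase,
acetate kinase) against hexokinase, phosphofructokinase and pyruvate
carboxylase. Oxidative ATP is computed from the oxygen uptake rate alone:
OUR × 2 O/O₂ × P/O with P/O = 2.5 mol ATP per mol O
(`atp_oxidative()`), so total ATP is exactly the sum of the two terms.
The exact substrate-level coefficient convention behind any particular
published figure is rarely stated; the set above is the conventional one,
and differing conventions shift the substrate-level total by a few
mmol/gDCW/h without affecting the oxidative term.

## Batch kinetics and carbon balance

`specific_rates()` estimates the specific growth rate as the
least-squares slope of log biomass versus time over a window (default:
after the 24-h DO split, where the two regimes diverge), the biomass
yield as the slope of biomass formed versus glucose consumed, and the
specific glucose uptake as μ / Y_X/S converted with the anhydrous glucose
molar mass (180.16 g/mol; media recipes list the monohydrate, but all
carbon arithmetic is molar and therefore unaffected, and the printed
uptake rates are consistent with the anhydrous conversion).
`carbon_balance()` computes recovery as the percentage of consumed
glucose carbon found in biomass, CO2, riboflavin and by-products;
riboflavin converts at 17 carbons and 376.36 g/mol. `pool_compare()`
performs per-metabolite Welch t-tests with a significance flag at 0.05
for metabolite-pool comparisons between conditions.

## The synthetic-data generator

`scenario_config()` fixes the study conditions of a batch: the `"H"`
(high DO) and `"L"` (low DO) profiles default to the measured kinetic
parameters of the two modes (qGlc 5.32/5.66 mmol/gDCW/h, qRib
0.054/0.038 g/gDCW/h, μ 0.092/0.035 1/h, Y_X/S 0.096/0.034, OUR
10.02/4.56, CER 9.52/4.47) and to oxidative-PP/TCA splits of 64.85/7.50
and 50.79/12.08 percent of uptake. `generate_flux_map()` solves for the
steady-state map pinned at those set-points; the remaining overflow
degree of freedom goes 60% to lactate on a mole basis (lactate and
acetate both accumulate in these fermentations; no separate rates are
printed, and the split is exposed as `lac_share`). Infeasible set-points
return the least-squares-nearest steady map with a distance attribute and
a warning.

`generate_mids()` adds independent Gaussian noise per mass channel (sd
0.004 mol fraction by default, typical GC-MS precision), clips at zero
and renormalizes — the standard error treatment for MID data — and
records the per-channel sd. `generate_timecourse()` produces exponential
growth from a 0.1 g/L inoculum with 40 g/L initial glucose (exhausted
just before 40 h under the H parameters, matching the observed
depletion), riboflavin accumulation proportional to biomass formed, a DO
trace high for 24 h then profile-specific (35% for H, 5% for L), and
three sampling-phase labels; optional multiplicative log-normal noise.

**Truth exchange fluxes and identifiability.** The magnitude of the
reversible-reaction exchange fluxes in the ground-truth maps is not a
measured quantity; the generator draws them uniformly between 0.05 and
0.25 × qGlc (moderate equilibration). This constant matters more than it
may appear: a Cramér–Rao analysis of the fitting problem shows that with
strongly equilibrated exchange (upper range 0.5 × qGlc and beyond,
especially phosphoglucose isomerase), the information bound on the
low-DO PP split exceeds 2 percentage points — no estimator could then
recover the split to that precision from this tracer, noise level and
fragment panel. The default is therefore set at the moderate level
consistent with the recovery performance the generator is specified to
support, and both bounds are exposed (`exch_lo`, `exch_hi`) so users can
study the degradation themselves. This is a genuine limitation of the
experiment design, not of the estimator: under high pool equilibration,
tighter split estimates require more positional tracer information (for
instance a higher [1-¹³C] fraction) rather than more replicates.

What the generator does *not* emulate: correlated channel errors from
overlapping GC-MS peaks, drift between batches, inaccurate
natural-abundance correction, day effects between the labeling
bioreactors, and any mismatch between the assumed and the true atom-map
network. Passing the synthetic-recovery suite therefore demonstrates
correctness and statistical calibration of the machinery under the
stated error model, not robustness to structural model error in real
data.

## Numerical choices, in one place

* Steady state enforced exactly by construction (null-space
  parameterization); post-hoc check |S·v| < 10⁻⁶ on fitted maps.
* EMU systems solved by dense LU; singular systems (zero-flux
  disconnected EMUs) are reported with the offending EMU names.
* Exchange coordinate bounded at ρ ≤ 0.9 (exchange ≤ 9 flux units);
  near-equilibrium exchange beyond that is indistinguishable from
  equilibrium within measurement noise.
* Optimization tolerances: SSR ftol 10⁻⁹, parameter ptol 10⁻¹⁰, at most
  150 LM iterations per start.
* Jacobian rank threshold for dof: singular values above 10⁻⁷ of the
  largest.
* Profile-CI bisection tolerance: 10⁻³ of the local flux scale; search
  window ±10 × the largest flux unless overridden.
* Reported-table rounding: respiratory quotient and recovery to 2
  decimals, matching the source tables.

## Problem sizes used in the validation suite

The shipped tests run the full pipeline at reduced but representative
sizes: the estimator calibration uses 20 seeded synthetic experiments
(two labeling replicates each, both DO profiles) with 8 optimization
restarts per fit; profile-interval coverage uses 100 replicates of a
five-reaction split/rejoin network; the isotopomer-enumeration oracle
covers networks up to 10 carbons. These sizes make the whole suite run in
minutes while keeping every statistical claim testable; all of them scale
up by changing one argument.

## Known limitations

* Atom mappings are the canonical ones; organism-specific deviations
  (e.g. promiscuous transketolase specificities) are not modeled.
* Isotopically nonstationary MFA, ¹⁵N/²H tracers and tandem-MS
  corrections are out of scope.
* The riboflavin and biomass drains are lumped; their MIDs are not
  simulated and must not be added as measured fragments.
* The substrate-level ATP figure depends on the coefficient convention
  described above; cross-study comparisons should verify the convention
  first.
* With fewer than two measured fragments per pathway branch the fit will
  warn about rank deficiency; intervals for the affected fluxes are
  open-ended by design.
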