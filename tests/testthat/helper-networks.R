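# Toy carbon-labeled networks used across the tests.  Input metabolites
# draw their labeling from the glucose tracer patterns (positions 1..n),
# so every toy input has at most 6 carbons.

toy_chain <- function() {
  # A(2) -> B(2) -> C(2) -> sink, no mixing
  flux_network(
    data.frame(id = c("A", "B", "C", "Z"), carbons = c(2, 2, 2, 2),
               role = c("substrate", "balanced", "balanced", "sink")),
    list(flux_reaction("r1", "A -> B", "ab : ab"),
         flux_reaction("r2", "B -> C", "ab : ab"),
         flux_reaction("r3", "C -> Z", "ab : ab")))
}

toy_reversible <- function() {
  # A(3) -> B(3) <-> C(3) -> sink; exchange on r2 mixes B and C pools
  flux_network(
    data.frame(id = c("A", "B", "C", "Z"), carbons = c(3, 3, 3, 3),
               role = c("substrate", "balanced", "balanced", "sink")),
    list(flux_reaction("r1", "A -> B", "abc : abc"),
         flux_reaction("r2", "B <-> C", "abc : cab"),
         flux_reaction("r3", "C -> Z", "abc : abc")))
}

toy_cleave_condense <- function() {
  # S(4) -> P(2) + Q(2); P + Q -> R(4) with swapped halves; R -> sink.
  # Also a direct S -> R route so R mixes a convolution with an intact EMU.
  flux_network(
    data.frame(id = c("S", "P", "Q", "R", "Z"), carbons = c(4, 2, 2, 4, 4),
               role = c("substrate", "balanced", "balanced", "balanced",
                        "sink")),
    list(flux_reaction("cleave", "S -> P + Q", "abcd : ab + cd"),
         flux_reaction("cond", "P + Q -> R", "ab + cd : cdab"),
         flux_reaction("direct", "S -> R", "abcd : abcd"),
         flux_reaction("out", "R -> Z", "abcd : abcd")))
}

toy_scramble <- function() {
  # symmetric intermediate: B is consumed through two equally weighted
  # mirror atom maps (succinate/fumarate-style molecular symmetry)
  flux_network(
    data.frame(id = c("A", "B", "C", "Z"), carbons = c(4, 4, 4, 4),
               role = c("substrate", "balanced", "balanced", "sink")),
    list(flux_reaction("r1", "A -> B", "abcd : abcd"),
         flux_reaction("r2", "B -> C", c("abcd : abcd", "abcd : dcba")),
         flux_reaction("r3", "C -> Z", "abcd : abcd")))
}

toy_parallel <- function() {
  # two indistinguishable parallel routes A -> B (identical atom maps):
  # the split between them is structurally non-identifiable
  flux_network(
    data.frame(id = c("A", "B", "Z"), carbons = c(3, 3, 3),
               role = c("substrate", "balanced", "sink")),
    list(flux_reaction("p1", "A -> B", "abc : abc"),
         flux_reaction("p2", "A -> B", "abc : abc"),
         flux_reaction("out", "B -> Z", "abc : abc")))
}

# split/rejoin with positional information: used for CI coverage studies.
# The split fraction is identifiable because route p2 permutes carbons.
toy_split_permute <- function() {
  flux_network(
    data.frame(id = c("A", "B", "C", "D", "Z"),
               carbons = c(3, 3, 3, 3, 3),
               role = c("substrate", "balanced", "balanced", "balanced",
                        "sink")),
    list(flux_reaction("p1", "A -> B", "abc : abc"),
         flux_reaction("p2", "A -> C", "abc : cba"),
         flux_reaction("j1", "B -> D", "abc : abc"),
         flux_reaction("j2", "C -> D", "abc : abc"),
         flux_reaction("out", "D -> Z", "abc : abc")))
}
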