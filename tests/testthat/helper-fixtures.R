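# Shared fixtures, built in code.

# Four-node chain: A feeds B and C, C feeds D. Trigger A collapses the
# whole network at alpha = 0.5.
toy_chain_network <- function() {
  generateToyNetwork(c("A", "B", "C", "D"),
                     edges = data.frame(source = c("A", "A", "C"),
                                        target = c("B", "C", "D"),
                                        logic = "DIRECT", weight = 0.5))
}

# Planted design with one triplet per logic family plus background genes.
planted_family_design <- function(seed, nSamples = 64, noise = 0) {
  plantedDesign(
    nGenes = 12, nSamples = nSamples, p = 0.5, noise = noise,
    seed = seed,
    relationships = list(
      list(inputs = c("g01", "g02"), target = "g03", logic = "OR"),
      list(inputs = c("g04", "g05"), target = "g06", logic = "AND"),
      list(inputs = c("g07", "g08"), target = "g09", logic = "XOR")))
}

# A triplet counts as recovered when an inferred triplet has the same
# unordered input pair and target; the logic label must agree up to
# complementation (complementary functions have identical uncertainty
# coefficients, so e.g. a planted XOR is reported as XNOR, which
# precedes it in the catalogue row order).
logic_complement <- c(AND = "NAND", NAND = "AND", OR = "NOR", NOR = "OR",
                      A_AND_NOTB = "NOTA_OR_B", NOTA_OR_B = "A_AND_NOTB",
                      NOTA_AND_B = "A_OR_NOTB", A_OR_NOTB = "NOTA_AND_B",
                      XOR = "XNOR", XNOR = "XOR")

find_planted <- function(net, truth_row) {
  tr <- secondOrderTriplets(net)
  ab <- sort(c(truth_row$inputA, truth_row$inputB))
  hit <- tr$inputA == ab[1] & tr$inputB == ab[2] &
    tr$target == truth_row$target
  tr[hit, , drop = FALSE]
}
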