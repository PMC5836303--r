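# LogicCascade

Robustness analysis of directed gene logic networks under
degree-strength cascading failures.

Gene logic networks model regulation among genes observed as binary
presence/absence profiles (e.g. detection calls from expression
microarrays): a first-order relationship A → C says one gene explains a
target, a second-order relationship f₂(A, B) → C says a Boolean
combination of two genes does. LogicCascade is for researchers who want
to (i) infer such networks from a 0/1 expression matrix, and (ii) ask
which single-gene deletions trigger large failure cascades — candidate
key genes in disease networks.

## The method

**Inference.** Every ordered pair is scored by the uncertainty
coefficient

U(C | A) = (H(A) + H(C) − H(A, C)) / H(C),

the fraction of the target's Shannon entropy explained by the source
(0 = independent, 1 = deterministic), and every triplet by
U(C | f₂(A, B)) for each of the ten two-input Boolean functions f₂.
Pairs are kept at U ≥ t₁, triplets at U ≥ t₂ when also stronger than
both first-order margins.

**Degree-strength accounting.** A triplet whose truth table has k
satisfying assignments adds k/2 to its target's in-degree (1/2 for the
AND family, 1 for XOR/XNOR, 3/2 for the OR family) and the same total
to its inputs' out-degrees, divided by a data-driven contribution split
((n₀+2n₁)/2(n₀+n₁+n₂) to A, (n₀+2n₂)/2(n₀+n₁+n₂) to B for OR-family
logic; equal halves otherwise). Degree strength weights each increment
by the relationship's U, so in/out totals are conserved exactly.

**Cascading failure (D-SCFM).** Each node's load is
in-strength/out-strength; its capacity is the interval
[(1−α)l, (1+α)l] around the initial load (points {0} and {+∞} for the
extreme loads). Deleting a trigger node removes its relationships;
loads are recomputed in synchronous rounds and every node whose load
leaves its initial capacity interval (or that becomes isolated) fails,
until a fixpoint. Damage is reported as size ratios dᵢ = sᵢ/N, their
maximum R_max, the survival curve P(d′ ≥ d), and a hub report joining
damage with degree, strength and logic-doublet motif counts
(both-in / both-out / in-out).

## Worked example

```r
library(LogicCascade)

gm <- generateMatrix(plantedDesign(
  nGenes = 8, nSamples = 64, seed = 11,
  relationships = list(
    list(inputs = c("g01", "g02"), target = "g03", logic = "OR"),
    list(inputs = c("g04", "g05"), target = "g06", logic = "AND"))))
net <- buildLogicNetwork(gm$matrix, t1 = 0.20, t2 = 0.35)
net
#> LogicNetwork: 8 nodes, 8 first-order edges, 4 second-order triplets
#>   thresholds: t1 = 0.2 , t2 = 0.35
secondOrderTriplets(net)
#>   inputA inputB target      logic    weight    splitA    splitB
#> 1    g01    g02    g03         OR 1.0000000 0.4777778 0.5222222
#> 2    g01    g03    g02 NOTA_AND_B 0.3734486 0.5000000 0.5000000
#> 3    g02    g03    g01 NOTA_AND_B 0.3536685 0.5000000 0.5000000
#> 4    g04    g05    g06        AND 1.0000000 0.5000000 0.5000000
```

Both planted triplets are recovered with weight 1 (a deterministic
target), with OR's contribution split estimated from the sample counts;
the two extra NOTA_AND_B triplets are echoes of the planted OR read in
the reverse direction. Now the robustness question:

```r
sw <- sweepAllTriggers(net, alpha = 0.5)
cascadeSummary(sw)$RMax
#> [1] 0.375
hubReport(net, sw, k = 3)
#>   gene s     d inDegree outDegree inStrength outStrength bothIn bothOut inOut
#> 1  g01 3 0.375      1.5  1.966667  0.4966385   1.1703854      1       3     6
#> 2  g02 3 0.375      1.5  2.033333  0.5392219   1.2723530      1       3     6
#> 3  g03 3 0.375      3.5  2.500000  2.2609591   0.8540811      3       6    12
```

The worst single deletion destroys 3 of 8 nodes (R_max = 0.375), and
the most damaging triggers are exactly the genes of the planted OR
module — the doublet-rich hub g03 and its two regulators. `alphaSweep()`
tabulates R_max over the capacity-parameter grid α = 0.1 … 0.9 (cascades
shrink as tolerance grows), and `thresholdSweep()` repeats the whole
pipeline over (t₁, t₂) pairs.

A thin command-line wrapper with `simulate | build | cascade | report`
subcommands is installed at
`system.file("scripts", "logic-cascade-cli.R", package = "LogicCascade")`.

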