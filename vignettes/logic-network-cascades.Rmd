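---
title: "Gene logic networks and degree-strength cascading failures"
author: "LogicCascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene logic networks and degree-strength cascading failures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LogicCascade)
```

## The model

LogicCascade studies the robustness of directed gene logic networks: how
the deletion of a single gene propagates through a network of Boolean
regulatory relationships inferred from binarized expression profiles.
The pipeline has three layers.

**1. Logic network inference.** The input is a genes x samples matrix of
0/1 calls (1 = gene present/expressed in a sample). For an ordered gene
pair the first-order uncertainty coefficient

$$U(C\mid A) = \frac{H(A) + H(C) - H(A,C)}{H(C)}$$

is the fraction of the target's Shannon entropy explained by the
candidate regulator: 0 for empirically independent profiles, 1 when the
target is a deterministic function of the source. For a gene triplet,
the two inputs are first combined elementwise by one of the ten
two-input Boolean functions $f_2$ (AND, OR, exclusive-or, equivalence,
and their negated-literal variants; `logicFunctions()` lists the
catalogue), and the same coefficient is computed for the composite
vector: $U(C \mid f_2(A,B))$. Relationships are retained when the
coefficient passes a first-order threshold $t_1$ (pairs) or a
second-order threshold $t_2 \ge t_1$ (triplets). Both coefficients are
invariant to the entropy log base (the ratio cancels it); we compute in
bits.

Two interpretive choices deserve a note. First, complementing a binary
vector leaves every entropy term unchanged, so a logic function and its
negation receive identical coefficients (AND vs NAND, XOR vs XNOR, a
direct regulator vs an inverted one). For pairs we therefore keep one
edge per ordered (source, target) and label it `DIRECT` when the two
profiles agree on at least half the samples, `INVERTED` otherwise. For
triplets we keep, per (input pair, target), only the type of maximal
coefficient, breaking ties by the fixed catalogue row order; a planted
exclusive-or consequently surfaces under the equivalence label, which is
the same relationship read through the complementary truth table.
Second, by default a triplet is retained only when its coefficient
strictly exceeds both of its first-order margins $U(C\mid A)$ and
$U(C\mid B)$ (`redundancyFilter = TRUE`), so second-order relationships
add information beyond their constituent pairs.

Constant genes have zero entropy and carry no regulatory signal; they
are excluded as targets with a warning, and a constant target's
coefficient is defined as 0 (configurable to an error).

**2. Degree and degree-strength accounting.** A two-input relationship
whose truth table has $k$ satisfying assignments ($k = 1$ for the
AND family, 2 for XOR/XNOR, 3 for the OR family) adds $k/2$ to the
in-degree of its target. The same total is added to the out-degrees of
the two inputs, divided by their *contribution split*: for OR-family
logic the split is estimated from the data as
$\left(\frac{n_0 + 2n_1}{2(n_0+n_1+n_2)},
\frac{n_0 + 2n_2}{2(n_0+n_1+n_2)}\right)$, where, among samples with
the target present, $n_0$ counts both input literals active, $n_1$ only
the first, $n_2$ only the second (literals are taken after the logic's
negations, the unique negation-covariant reading). For the AND family
the inputs act jointly and for XOR/XNOR the data cannot apportion the
regulation, so the split is $(\tfrac12, \tfrac12)$. An OR-family triplet
whose support counts are all zero falls back to the equal split with a
warning. Single-input edges add 1 to both endpoints. Degree totals are
thus conserved by construction: the summed in-degree equals the summed
out-degree on every network.

Degree *strength* is the U-weighted analogue. We scale each
relationship's weight by the same increments on both sides (the target
gains $U \cdot k/2$, the inputs gain $U \cdot \text{split} \cdot k/2$),
so strength conservation mirrors degree conservation exactly. Summing
the raw weight on the in-side but the split-scaled weight on the
out-side — a literal reading of the strength definition that implicitly
assumes $k = 2$ — would break conservation for the AND and OR families;
conservation is stated as a design axiom of the accounting, so we treat
the increment scaling as the intended general form. This is the one
place where the package resolves a genuine ambiguity in the accounting's
definition; the choice is asserted by property tests on every random
network.

**3. The cascade (D-SCFM).** The load of a non-isolated node is the
ratio of its in-strength to its out-strength: 0 for a pure regulator,
$+\infty$ for a pure target, positive otherwise. Its capacity is the
load interval it tolerates, $[(1-\alpha)l, (1+\alpha)l]$ for finite
positive $l$, with the point conventions $\{0\}$ and $\{+\infty\}$ for
the extreme loads. (The source account prints $(1-\alpha)l$ for both
limits; a degenerate interval would make every perturbed node fail at
any $\alpha$, so the upper limit is implemented as the symmetric
$(1+\alpha)l$.) The capacity parameter $\alpha \in (0,1)$ is the
relative half-width: the single tunable knob of the simulation, with
small $\alpha$ meaning brittle nodes.

A cascade is triggered by deleting one node and all relationships it
participates in (a triplet dies with any of its three genes). Failure
then propagates in *synchronous rounds*: the loads of all surviving
nodes are recomputed on the current network and compared with their
*initial* capacity intervals, fixed once from the intact network —
"initial capacity" is otherwise undefined for nodes other than the
trigger. All violating nodes are removed together, which makes the
update order-independent and deterministic; nodes isolated by the
cascade fail as well by default (a node with no relationships can no
longer operate in a logic network), though `isolatedPolicy = "inert"`
keeps them for sensitivity analysis. Nodes isolated in the *intact*
network have no load, never fail, and stay in the denominator $N$.
The failed set grows strictly every round, so the fixpoint is reached
in at most $N$ rounds.

Damage is summarized per trigger by the size ratio $d_i = s_i/N$
(failed nodes over network size, trigger included), over triggers by
$R_{\max} = \max_i d_i$, and distributionally by the cumulative cascade
probability $P(d' \ge d)$, the empirical survival function of the
$d_i$. Logic *doublets* — pairs of relationships sharing a center node
— are classified `both-in`, `both-out` or `in-out` by the center's
role, with characteristic doublet-subgraph loads $+\infty$, 0 and
positive; `hubReport()` joins the damage ranking with degree, strength
and doublet counts to expose the hub-motif structure behind large
cascades.

## Numerical choices

* Interval membership uses a relative tolerance of $10^{-9}$ at finite
  capacity boundaries: strengths are sums of coefficients, and exact
  boundary hits are floating-point artifacts, not biology.
* Load class transitions are checked structurally: a node whose initial
  load is 0 fails only when its (necessarily zero) load class changes,
  i.e. when it becomes isolated; an initially $+\infty$-load node fails
  only when isolated, since its out-strength cannot increase.
* Uncertainty coefficients are clamped into $[0,1]$ against round-off.
* All enumeration orders (pairs, triplets, trigger sweeps, file output)
  are lexicographic, making every artifact byte-reproducible.

## The synthetic-data generator

Real inputs for this kind of analysis are presence/absence calls from
expression microarrays, pre-filtered to tens of genes. The generator
(`plantedDesign()` / `generateMatrix()`) emulates that substrate:
background genes are i.i.d. Bernoulli($p$) across samples (default
$p = 0.5$, the entropy-maximizing rate, and the simplest null under
which coefficients of unrelated genes vanish as samples grow), and each
planted relationship computes its target from the realized inputs
through the logic truth table, then flips each target entry with
probability $\varepsilon \in [0, 0.5)$ — a measurement-noise reading
that leaves the inputs untouched (an input-noise mode exists). Defaults
used throughout the tests: 12 genes, 64 samples, one planted triplet
per logic family, $\varepsilon = 0$ for recovery checks. The generator
does *not* emulate probe-level signal, inter-gene correlation beyond
the planted logic (a block-correlated background would be a natural
extension), or the differential-expression pre-selection applied to
real cohorts — so passing recovery tests demonstrate correctness of the
inference machinery, not field performance on microarray data.

`randomLogicNetwork()` generates structurally valid networks directly
(uniform endpoints without duplicates, uniform weights on [0.1, 1],
uniform logic types, uniform OR-family splits) for the conservation,
oracle-agreement and robustness ensembles; 15 nodes with 18 edges and
12 triplets matches the density regime of thresholded real networks at
desk scale, and 3–6-node graphs are used where an independent
brute-force oracle re-runs every cascade.

## Worked example

```{r example}
gm <- generateMatrix(plantedDesign(
  nGenes = 8, nSamples = 64, seed = 11,
  relationships = list(
    list(inputs = c("g01", "g02"), target = "g03", logic = "OR"),
    list(inputs = c("g04", "g05"), target = "g06", logic = "AND"))))
net <- buildLogicNetwork(gm$matrix, t1 = 0.20, t2 = 0.35)
net
secondOrderTriplets(net)
sm <- cascadeSummary(sweepAllTriggers(net, alpha = 0.5))
sm$RMax
hubReport(net, sweepAllTriggers(net, alpha = 0.5), k = 3)
alphaSweep(net)
```

The problem sizes used in the test-suite ensembles (100 random networks
for conservation, 500 small graphs for oracle agreement, 50 networks
by 9 capacity values for the robustness trend, 20 seeds for recovery)
were chosen as the smallest ensembles at which the stochastic
properties are stable across reruns.

## Known limitations

* Inference is $O(G^3)$ in the gene count with ten coefficient
  evaluations per triplet; the intended regime is the tens-of-genes
  scale that follows differential-expression pre-filtering.
* No significance calibration: thresholds on $U$ are structural
  parameters, not error rates. FDR control or bootstrap edge confidence
  would be needed before biological claims.
* Direction of a first-order edge is a modelling convention (the
  numerator of $U$ is symmetric; only the normalization is directional).
* Complement-equivalent logic labels are not distinguishable from
  binary profiles, only the equivalence class is identifiable.
* The cascade model redistributes nothing: failure is a property of a
  node's own load leaving its tolerance band, not of flow rerouting;
  edge-capacity and efficiency-based models are out of scope.
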