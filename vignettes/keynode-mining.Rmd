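---
title: "Community-constrained key-node mining in weighted co-occurrence networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community-constrained key-node mining in weighted co-occurrence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acunet)
```

## The network model

`acunet` studies networks induced by *prescription tables*: each condition
(a disease, in the acupuncture setting the package grew out of) maps to a
small set of entities (acupoints) prescribed together. The modelling
assumption is that co-prescription is evidence of synergy, so every
prescription induces a fully connected subnetwork among its entities, and
the weight of an edge is the number of conditions whose prescriptions
contain both endpoints. With `n` conditions, weights are integers in
`[0, n]`, and the network is the superposition of `n` cliques. A typical
corpus — around 50 conditions, up to 10 entities each, drawn from roughly
135 entities with strongly skewed popularity — yields a small, dense,
hub-dominated network.

Two structural choices follow from that reading:

* **Counting conditions, not mentions.** Duplicated (condition, entity)
  rows are collapsed with a warning; a pair co-occurring in one condition
  contributes exactly 1 to its weight however often the rows repeat.
* **Hops, not weights, for distance.** Edge weights are co-occurrence
  counts — similarities, not lengths — so all shortest-path quantities
  (closeness, betweenness, the diameter `D`, deletion-loss distances) use
  unweighted hop counts. Weights enter only where the model calls for them:
  matrix powers, weighted degree, and the weight-reduction benchmark.

Entities listed in the community map but absent from every prescription are
excluded from the network: the node set is defined by the prescriptions.
Disconnected networks can be built (and are flagged), but every operation
whose definition presumes connectivity — closeness, diameter, the influence
index, deletion loss — refuses them by design rather than returning a
convention-dependent number.

## The influence index

For the weighted adjacency matrix `A`, the entry `A^k[i, m]` sums the
products of edge weights over all length-`k` walks from `i` to `m`. Writing
`theta_i^k` for the off-diagonal row sum (node `i`'s weighted influence at
walk length `k` — at `k = 1` exactly the weighted degree) and `theta^k`
for half the total off-diagonal mass (each unordered pair once), the index
is

```
Key_node(v_i) = sum over k = 1..D of theta_i^k / theta^k
```

with `D` the hop diameter. The index is a *share*: at each walk length a
node receives its fraction of the network's total walk influence, and the
fractions are summed out to the diameter. Since row totals double the pair
total at every `k`, the scores always sum to `2 D` — a sharp identity the
test suite checks on random weighted graphs, and a useful smoke test for
any reimplementation.

Walk semantics are taken literally from the matrix power: walks may revisit
nodes and edges, so a heavy edge contributes at every length. That is the
only reading consistent with defining the index through `A^k`; a
"path" (non-revisiting) semantics would not factor through matrix powers at
all. One practical consequence, visible in the test fixtures: a node whose
single heavy edge links it to an otherwise peripheral partner can outrank
nodes of much better closeness, while a node *concentrating several* heavy
edges cedes part of its length-2 influence to its neighbours, because its
own closed walks (the diagonal of `A^2`) are excluded.

Powers are computed by repeated dense multiplication. Networks here are
small (N of order 10^2) and `D` is rarely above 4, so the cost is
negligible; no eigendecomposition shortcut is used, keeping results exact
for integer weights at small `k`.

## The two-stage mining pipeline

Communities are fixed node attributes (meridians in the original setting),
never detected: the method is about respecting a known anatomical
partition, and detected communities would answer a different question.

1. **Candidates.** Each community contributes its `per_community = 4` nodes
   of highest closeness centrality; smaller communities contribute all
   their nodes. With 15 communities the candidate set is at most 60.
2. **Keys.** Within each community the candidates are re-ranked by
   `Key_node` and the top `per_community = 2` are kept, giving 30 key nodes
   when every community has at least two candidates.

The closeness pre-filter is part of the method, not an optimization: it
anchors the key set to globally central nodes before the weight-sensitive
index reorders them, and a candidate that was only third or fourth by
closeness can and does win the key stage.

Ties are broken by higher score, then higher weighted degree, then
lexicographic entity id. The rule is total, so every selection is
deterministic and reproducible; the score values themselves are left tied
(resolution, below, measures exactly that).

For fair comparison, baseline methods (degree, closeness, betweenness,
eigenvector, k-shell, clustered local degree) pick their per-community
top-2 directly by their own score, without the closeness pre-filter — the
pre-filter encodes the proposed method's design and would contaminate the
baselines.

## Evaluation indexes

**Resolution.** Scores are grouped into `R` equal-value classes and
`f = 1 - sum(N_i^2) / (R n^2)`; a constant ranking scores 0, all-distinct
scores reach the maximum `1 - 1/n^2`. Scores are compared after rounding
to 10 significant digits — without it, floating-point noise would make
every centrality appear perfectly resolving. `f` is invariant under
strictly monotone transforms, so it measures the ranking, not the scale.

**Deletion loss.** Deleting a node loses its own connections (DLOS: sum of
reciprocal hop distances from the node) and possibly severs surviving pairs
(ILOS: sum of reciprocal distances over pairs disconnected by the
deletion). Distances are always taken in the *original* network — after
deletion the severed distances are infinite and the quotient would be
meaningless. `TLOS = DLOS + ILOS` is normalized by the star-center maximum
`(N-1)(N+2)/4`, so `C = 1` exactly for the center of a star of any size.
For a *set* deletion the same definitions apply with all targets removed
simultaneously: DLOS counts each unordered pair with at least one deleted
endpoint once (including deleted–deleted pairs), ILOS the severed surviving
pairs, and the single-node normalizer is retained so set losses are
comparable across methods on the same network. Simultaneous rather than
sequential deletion is the natural reading of "delete the key set", and
keeping the single-node normalizer makes `C(U)` a bounded, size-honest
quantity; both choices are conventions and are stated here because the set
extension is genuinely underdetermined.

**Weight-reduction benchmark.** For each node `v`, every edge is assigned
length 2 except the edges incident to `v`, which get length 1; `l_v` is the
mean weighted shortest-path length over all unordered pairs (including
pairs not involving `v` — it is the network's average distance, not the
node's). The benchmark score is `W(v) = s_v / l_v` with `s_v` the weighted
degree in the *original* network: the modified lengths probe position, the
original weights supply magnitude. Method rankings are compared to `W` with
Kendall's tau in the tie-aware tau-b form (`stats::cor`), since several
baselines — k-shell above all — are heavily tied and a tie-naive tau would
be undefined up to tie ordering.

## Numerical choices

* **Eigenvector centrality** is computed by power iteration on `A`
  (tolerance 1e-10 on the L2 step change, at most 10,000 iterations,
  L2 normalization, nonnegative orientation). A diagonal shift of
  `max(rowSums(A))/2` is applied during iteration: it leaves the principal
  eigenvector unchanged but prevents the oscillation between the `+lambda`
  and `-lambda` eigenspaces on bipartite graphs (a path graph never
  converges without it). The shift is proportional to the matrix scale, so
  the iteration — like the eigenvector itself — is invariant under
  rescaling all weights.
* **CLD** has no universally fixed formula; the default
  `CLD(i) = sum of neighbour degrees / (1 + c_i)` (local clustering `c_i`,
  0 where undefined) implements its verbal description — neighbourhood
  strength tempered by clustering — and the combination rule is a pluggable
  function argument for users who prefer a different published variant.
* **k-shell** is the classic unweighted decomposition (`igraph::coreness`);
  weights are deliberately ignored.

## The synthetic generator

The original corpus behind this method is not available in machine-readable
form, so the package ships a generator that emulates its structure rather
than its values: 50 conditions, 135 entities, 15 communities, 10 entities
per prescription, and Zipf-skewed entity popularity (exponent 1) drawn over
a seed-derived random permutation so that popularity is independent of
community labels. The default `"auto"` community profile gives two
communities only 2 entities — mirroring meridians that contribute only a
couple of prescription points — and balances the rest. If the induced
network is disconnected the table is resampled (bounded retries) and, as a
last resort, a single bridging condition joining one entity per component
is appended, with a message.

What the generator does *not* emulate: the real corpus' exact degree
sequence, its specific hub identities, or any clinically meaningful
co-occurrence pattern — entities are exchangeable apart from popularity
rank. Passing tests therefore demonstrate the correctness and stability of
the algorithms on structurally faithful input, not the clinical
conclusions drawn from the original data. With default settings not every
configured entity appears in some prescription, so the induced network
typically has slightly fewer nodes than entities — matching the rule that
prescriptions define the node set.

## Problem sizes and limitations

The test suite and the acceptance script run the full pipeline on networks
of roughly 30–135 nodes and property checks on batches of up to 100 random
graphs of up to 40 nodes — the scale the method targets; everything
completes in seconds. The implementation is deliberately dense-matrix and
exact, and is not intended for networks beyond a few thousand nodes: matrix
powers, all-pairs distances per node in the benchmark, and the O(N^2) loss
sums all scale accordingly. Other known limitations: the influence index is
only defined on connected networks; community labels must be supplied, not
inferred; and the set-deletion loss convention, while internally
consistent, is one of several defensible extensions of the single-node
definition.
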