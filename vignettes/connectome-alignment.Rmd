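---
title: "Comparing and aligning weighted brain networks with connalign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing and aligning weighted brain networks with connalign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connalign)
```

## The problem

A structural connectome is a weighted undirected graph: nodes are brain
parcels defined by an atlas, and each edge weight encodes the strength
of the white-matter connection between two parcels (here, normalised
streamline counts from tractography). Two connectomes built from
different subjects — or with atlases of different granularity — do not
come with a node correspondence, and even when one exists it is useful
to ask *how similar* two such networks are. `connalign` addresses both
questions:

* **Similarity**: the *weighted graph Jaccard index* (GJI), a
  Ruzicka-type similarity between equal-sized weighted graphs, together
  with the classical Frobenius / $\ell^p$ distances and the uncentred
  cosine similarity.
* **Alignment**: *WL-align*, a Weisfeiler–Leman-inspired algorithm that
  summarises every node by a fixed-length signature of its strongest
  weighted paths and recovers a node correspondence by minimum-cost
  bipartite assignment.

## Similarity measures

For two connectomes $G_1$, $G_2$ on the same node set with adjacency
matrices $A$ and $B$, the GJI is

$$J(G_1, G_2) =
  \frac{\sum_{(i,j)} \min(A_{ij}, B_{ij})}
       {\sum_{(i,j)} \max(A_{ij}, B_{ij})},$$

the sums running over all unordered node pairs. We take the pair set to
include self-pairs; since preprocessing zeroes the diagonal this is
equivalent to excluding them, and it makes $J$ exactly the weighted
Jaccard (Ruzicka) similarity of the vectorised upper triangles. $J = 1$
iff the adjacencies coincide, $J = 0$ iff the graphs share no edge, the
index is undefined when both graphs are empty (the package raises an
error rather than returning a sentinel), and $d_J = 1 - J$ is a true
metric — identity and symmetry are immediate, and the triangle
inequality is inherited from the vector case. The suite verifies the
axioms on $10^4$ random graph triples.

`normDistance` and `cosineSimilarity` implement the two classical
alternatives. Cosine similarity is deliberately *uncentred* — the plain
scalar product of the vectorised adjacencies over the product of their
norms — which is how the quantity is used in connectomics even when it
is informally called "correlation"; users expecting Pearson should
centre their data themselves. Vectorisation uses the full matrix; for
symmetric matrices this equals upper-triangle vectorisation up to a
factor that cancels in the cosine.

## Preprocessing conventions

Raw streamline-count connectomes go through three rules, in this order:

1. **Negative thresholding** (`thresholdNegative`) for matrix types
   that can go negative; entries below zero are replaced by zero.
2. **Isolated-node repair** (`repairIsolatedNodes`): every zero-volume
   node is connected to *all* other nodes — including other formerly
   isolated ones — with weight 1 on the raw count scale, the equivalent
   of a single streamline. Applied before normalisation.
3. **Weight normalisation** (`normalizeWeights`): all weights divided
   by the sum of the weights in the graph. We interpret "the sum of the
   weights" as the sum over *unique undirected edges* (the upper
   triangle); any consistent convention rescales all graphs identically
   and cancels from every relative quantity, and the unique-edge sum
   matches the per-streamline semantics of the counts. Under this
   convention the Frobenius distance between two normalised connectomes
   is bounded by 2 (each entry is at most 1, and the entrywise absolute
   differences sum to at most 4), which the suite checks on $10^3$
   random pairs.

Symmetry is enforced with an absolute tolerance of $10^{-12}$: inputs
within tolerance are symmetrised by averaging, larger asymmetries are
rejected. Alignments are stored by node label, never by index, so maps
survive node reordering and per-hemisphere merging.

## WL-align

### Node signatures

The volume of a node is its weighted degree,
$\mathrm{vol}(v) = \sum_u w_{uv}$. A path
$\pi = (v_0, \ldots, v_h)$ contributes

$$f(\pi) = \Big(\prod_{i=0}^{h-1}
  \frac{w(v_i, v_{i+1})}{\mathrm{vol}(v_i)}\Big)\,
  \mathrm{vol}(v_h),$$

the terminal volume damped by weight/volume ratios along the way. The
signature $H_u$ of node $u$ is built by a FIFO breadth-first expansion:
starting from the zero-length path $(u)$, each popped path appends its
$f$ to $H_u$ and, while shorter than $\ell$ hops, is extended by
**every** node of the graph; the $k$ extensions of largest contribution
are kept, ranked in descending order with ties broken uniformly at
random. The result has exactly $d = \sum_{i=0}^{\ell} k^i$ entries,
the first being $\mathrm{vol}(u)$.

Three design points deserve a note:

* **Revisits are allowed.** The extension universe is all nodes,
  including the path's own predecessors — the expansion schedule is a
  complete $k$-ary tree, not a visited-set BFS. The closed forms for
  the worked example (`signatureExampleGraph`) confirm this reading:
  the fourth entry of the example signature is the contribution of the
  path that steps from $u$ to its strongest neighbour and straight
  back.
* **Degenerate volumes.** If an intermediate node has zero volume the
  contribution is defined as 0 (such a path necessarily crossed a
  zero-weight edge). Isolated-node repair makes this unreachable on
  preprocessed data. When fewer than $k$ extensions exist (width
  larger than the graph), the expansion is padded with zero-contribution
  entries, consistent with the non-edge $\Rightarrow f = 0$ rule.
* **Ties.** Tie-breaking uses a dedicated seeded stream
  (`withr::with_seed`), restarted per node so a single-node
  `wlSignature` call reproduces the corresponding `signatureTable` row
  exactly. With continuous weights ties have probability zero; integer
  (streamline-count) weights can tie often, which degrades
  reproducibility across seeds — the synthetic generators default to
  continuous weights for precisely this reason.

### Assignment

Signatures of the two graphs define a complete bipartite graph whose
edge weights are Euclidean signature distances
$b(u, v) = \lVert H_u - H_v \rVert_2$; the alignment is the bijection
minimising $\sum_u b(u, m(u))$. `solveAssignment` delegates the
minimum-cost matching to exact maximum-weight bipartite matching in
`igraph` on the complemented costs ($\max(b) + 1 - b$, all weights
positive, so a maximum-weight matching is row-perfect and cost-minimal);
the suite cross-checks it against brute-force enumeration on 500 random
cost matrices up to $7 \times 7$. Rectangular problems
($n_1 < n_2$) are solved by the same reduction and yield an injection.

The default width is $k = \lfloor \log_2 n \rfloor$, clamped to
$[1, n-1]$, with $n$ the node count of the network being aligned — for
hemisphere-wise alignment (`wlAlignHemispheres`), each hemisphere's own
node count. Depth defaults to $\ell = 2$: deeper entries are damped
geometrically, so extra depth buys little. Hemisphere-wise alignment
takes induced subgraphs: interhemispheric edges are dropped entirely,
so volumes inside a hemisphere count within-hemisphere connectivity
only (whether interhemispheric mass should be retained in volumes is a
modelling choice; the induced-subgraph convention is the simplest
self-consistent one and is what the package implements).

## Alignment quality

Against a known ground truth $m^*$, a computed alignment $m$ is scored
by the node matching ratio
$\mathrm{NMr} = |\{u : m(u) = m^*(u)\}| / |V_1|$, the GJI of the
aligned pair $J(m)$, the Jaccard ratio $Jr = J(m)/J(m^*)$ (which
normalises for how dissimilar the pair is intrinsically; it is bounded
by 1 whenever $m^*$ is GJI-optimal, which `bruteForceAlignment` can
certify for $n \le 8$), the Frobenius distance after relabelling, and
cosine similarity. `cohortExperiment` evaluates every unordered pair of
a cohort, self-pairs included, aligning subject $i$'s connectome
against subject $j$'s randomly permuted one — the self-pair is then
literally a subject versus a permuted copy of itself. Cohort averages
are plain arithmetic means; aligner failures become `NA` rows and are
reported, not dropped. Per-node correctness indicators are retained so
`selfMatchingRate` can report which regions are matched reliably, and
the per-pair table is exported so any standard paired test (e.g.
Wilcoxon signed-rank via `stats::wilcox.test`) can be run downstream —
the package deliberately does not wrap the statistics itself.

## What the synthetic generators emulate

No imaging data ships with the package; all validation runs on
generated graphs.

* `randomConnectome` draws connected graphs with lognormal (default),
  uniform, or integer streamline-count weights. Defaults — density 0.6,
  lognormal log-sd 1 — mimic the density and dynamic range of
  low-resolution structural connectomes. Lognormal continuous weights
  guarantee almost-surely strict expansion rankings, isolating
  WL-align's behaviour from tie-breaking randomness; the integer model
  exists to stress-test tie handling.
* `permuteConnectome` relabels nodes and keeps the permutation as a
  ground-truth `Alignment`; with hemisphere tags the permutation acts
  within hemispheres.
* `perturbWeights` applies i.i.d. multiplicative lognormal noise per
  edge and renormalises. Multiplicative (not additive Gaussian) noise
  respects positivity and the orders-of-magnitude weight spread.
* `multiresolutionCohort` emulates a cohort seen through atlases of
  increasing granularity: a latent fine-grained graph, per-subject
  multiplicative *node* strength factors, and Poisson streamline-count
  sampling at a fixed budget, aggregated into parcel blocks per
  resolution. The node factors are spatially coherent, so they survive
  aggregation (i.i.d. per-edge noise would be averaged away by block
  sums and make the Frobenius trend flat — the reason this generator
  perturbs nodes, not edges); the finite count budget makes fine
  parcellations relatively noisier. Together these reproduce the
  characteristic inversion: as the parcel count grows, the mean
  pairwise Frobenius distance *and* the mean pairwise GJI both
  decrease — Frobenius because absolute weights shrink, GJI because
  relative sampling noise grows.

What passing these tests does **not** show: the generators make no
attempt to match real connectome weight distributions quantitatively,
contain no geometry or left–right anatomical symmetry, and their
noise model is far simpler than inter-subject anatomical variability.
Trend *directions* and exact-recovery properties transfer to real
data; absolute metric values do not.

## Numerical choices and problem sizes

* Symmetry tolerance $10^{-12}$ absolute; symmetrisation by averaging.
* Signature distances are computed directly as
  $\sqrt{\sum (H_u - H_v)^2}$ per row pair rather than via the
  Gram-matrix expansion, so identical signatures give exactly zero
  cost.
* Matrix-CSV output prints 17 significant digits, making the
  round-trip bit-compatible.
* The validation suite runs WL-align at $n = 68$ (a Desikan-sized
  network) over 20 seeds for the exact-recovery property, $10^4$
  triples for the metric axioms, $10^3$ pairs for the Frobenius bound,
  and 500 matrices for the assignment oracle; these sizes keep the full
  suite under a minute on one core while leaving each property's
  operative regime intact.

## Worked example

```{r example}
g <- normalizeWeights(randomConnectome(68, density = 0.6, seed = 1))
p <- permuteConnectome(g, seed = 2)
m <- wlAlign(g, p$connectome)
nodeMatchingRatio(m, p$truth)
jaccardOfAlignment(m, g, p$connectome)
frobeniusOfAlignment(m, g, p$connectome)
```

A noisy pair no longer admits a perfect score, but WL-align stays far
above a random matching:

```{r noisy}
noisy <- perturbWeights(g, 0.3, seed = 3)
pn <- permuteConnectome(noisy, seed = 4)
mn <- wlAlign(g, pn$connectome)
c(nmr = nodeMatchingRatio(mn, pn$truth),
  gji = jaccardOfAlignment(mn, g, pn$connectome),
  gji_truth = jaccardOfAlignment(pn$truth, g, pn$connectome))
```

## Known limitations

* Equal-sized graphs only; unequal sizes would need cluster-level
  correspondence, which is out of scope.
* Non-negative weights only; signed, directed and temporal networks are
  not supported.
* Integer-weighted graphs can tie in the expansion ranking; results
  then depend on the tie-breaking seed.
* The FAQ graph-matching baseline is not reimplemented; the evaluation
  harness accepts any external aligner as a plain R function.
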