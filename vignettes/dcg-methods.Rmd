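---
title: "Multi-scale ultrametric trees from regulated random walks"
author: "DCGtree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale ultrametric trees from regulated random walks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DCGtree)
```

## The problem

Agglomerative hierarchical clustering (HC) builds a tree from the bottom
up, and its first, smallest-distance merges are the most sensitive to
measurement noise; a different starting dyad can propagate into a very
different tree.  DCGtree takes the opposite route: it treats the empirical
similarity matrix $S$ as a weighted graph, reads off the *multi-scale*
organization of that graph by varying a single temperature-like parameter,
and only then assembles a tree.  The output is an ultrametric — a distance
satisfying the strong triangle inequality
$u(i,k) \le \max(u(i,j), u(j,k))$ — which is exactly the class of
distances representable as a rooted tree with leaf heights.

## The model

**Potential landscape.**  Given node similarities $S_{ij} \in [0,1]$ and a
temperature $T > 0$, each link carries the Boltzmann weight

$$W_{ij}(T) = S_{ij}^{1/T} = \exp(-E_{ij}/T), \qquad E_{ij} = -\log S_{ij},$$

with $W_{ii} = 0$.  Large $T$ flattens the landscape (every positive weight
approaches 1); small $T$ amplifies the contrast between strong and weak
links, deepening the potential wells.  The ordering of the entries of $S$
is preserved at every temperature.  Distance matrices enter through
$S = \exp(-D/\sigma)$ with $\sigma$ the median off-diagonal distance by
default; because $E = D/\sigma$ and the temperature grid is expressed in
units of the median link energy, the choice of $\sigma$ only fixes units
and does not change the dynamics on the grid.

**Regulated random walk.**  A Markov chain with transition matrix
$P = \Delta^{-1} W$ ($\Delta$ the diagonal of row sums) would simply mix;
to map the wells we regulate it: every arrival increments the current
node's visit count, and a node whose count reaches the cap $m$ (default 5)
is removed, the elapsed arrivals since the previous removal are recorded
(its *recurrence time*), the transition matrix is renormalized over the
remaining nodes, and the chain continues with one Markov step from the
removed node's row.  Removal-by-cap empties one well after another, so
total arrivals are bounded by $Nm$ and the walk always terminates.  When a
walk first enters a fresh well all counts there are zero, so the next
removal takes unusually long: recurrence-time *spikes* mark well
boundaries.  A position is a spike when its recurrence time exceeds
$c = 5$ times the running median of all earlier recurrence times (the
median is robust to the heavy-tailed intra-well recurrence distribution;
the first removal has no baseline and is never a spike).  Nodes removed
between consecutive spikes are recorded as sharing a well, giving a binary
co-well matrix per walk.

Two details are deliberate.  The chain continues after a removal with a
*weight-proportional* step from the removed node's row: a uniform choice
among positive-weight neighbors would hop across vanishingly weak links
(weights of order $10^{-12}$ still count as positive) and destroy the
well-exhaustion behavior the regulation exists to produce.  And the walk
ends when one node remains, which that node joins the record with the
arrivals since the prior removal; as a consequence the last node of the
first-exhausted well is occasionally stranded below its cap and appears
out of block order — an intrinsic, measurable cost of the cap rule
(roughly a quarter of walks on a two-block toy instance), diluted by
ensemble averaging.

**Cluster-sharing probability matrix.**  Averaging the co-well indicators
of $E = 50$ independent walks gives $\hat P(T)$, a consensus matrix whose
$(i,j)$ entry estimates the probability that $i$ and $j$ inhabit the same
well at temperature $T$.  Its eigen-spectrum counts the wells: a well of
$s$ nodes sharing with probability $p$ contributes an eigenvalue near
$s p$, while the unit diagonal alone sustains a noise floor near 1, so we
take $K(T)$ = the number of eigenvalues at or above $5\%$ of the leading
one.  We chose this counting rule over a largest-gap rule after observing
that the gap $\lambda_1 - \lambda_2$ dominates as soon as cross-sharing is
appreciable, which reads every mid-temperature spectrum as $K = 1$ and
erases the intermediate scales entirely; the counting rule is exact on
block-constant matrices (eigenvalues = block sizes followed by zeros) and
returns $N$ on the identity.

Memberships at a given $K$ are extracted by cutting an average-linkage
tree of the distance $1 - \hat P$ — the standard way consensus-clustering
reads a co-clustering matrix.  We measured this to be markedly more robust
to single bridge nodes than spectral K-means (which remains available via
`method = "spectral"`, as does literal K-means on the rows of
$1 - \hat P$ via `method = "raw"`).

## Phase transitions and the temperature scan

$K(T)$ decreases in plateaus separated by phase transitions.  The scan
evaluates a geometric grid of 24 temperatures spanning $[0.05, 5]$ times
the median link energy, extends the grid upward (doubling, at most 10
times) until $K$ reaches 1, and then *refines* any plateau shorter than
`plateauMin = 2` grid points by inserting geometric midpoints at its
boundaries (up to 3 rounds).  The refinement matters: a 24-point grid over
a 100-fold temperature range only resolves phases spanning at least
$100^{2/23} \approx 1.49$ in temperature, while genuinely meaningful
phases (the three-cluster phase of the five-dots benchmark below spans
roughly 1.2–1.5) can otherwise be lost to sampling.  A real phase gains
support under refinement; a one-point fluctuation stays short and is
dropped.

Each kept plateau becomes one level of the hierarchy.  Its
*representative temperature* is the plateau's largest grid point — the
barrier top just before the next merge, which is the natural energy-barrier
height for the ultrametric (the single-cluster level therefore sits at the
top of the grid).  Its *representative configuration* is extracted from
the plateau-pooled sharing matrix (element-wise mean over the plateau's
grid points): at the plateau top the next merge is already imminent and
memberships begin to mix, while pooling uses the walk ensembles of the
whole phase.  Finally, working from the hottest level down, levels are
de-duplicated so that $K$ strictly decreases as $T$ increases.

## The self-correcting ultrametric

For each node pair and each critical level $l = 1 \dots k$ the status
sequence $\delta_l \in \{0, 1\}$ records co-clustering at that level.  The
barrier height of a pair is the temperature of the *last* 0-to-1 switch of
its sequence (pairs never separated take the bottom temperature $T_1$).  A
sequence may switch more than once when level configurations are not
nested; the rule then revises the earlier co-cluster assignments upward —
the built-in self-correction.  Because a pair stays co-clustered after its
last switch and each level is a partition, the resulting matrix satisfies
the strong triangle inequality for *any* level sequence, nested or not
(if $i \sim j$ and $j \sim k$ from level $\max(l^*_{ij}, l^*_{jk})$ on,
then $i \sim k$ there too).  The implementation nevertheless applies the
subdominant-ultrametric (minimax-path, single-linkage) closure: it is the
identity on partition-derived heights, and it repairs status arrays
supplied directly by a user that break within-level transitivity.

Thresholding the ultrametric at each level temperature recovers nested
partitions; these form the DCG tree, exported as Newick with branch
lengths equal to height differences, so the tree's cophenetic matrix
reproduces the ultrametric exactly.  Re-indexing the ultrametric along a
depth-first traversal of the tree (children ordered by size, ties by
smallest member index) yields the Parisi matrix, in which every cluster of
every level occupies a contiguous index range and the block-constant
structure is visible by eye (`plotParisi()`).

## Synthetic benchmarks

`fiveDots()` places five centers on a line at successive gaps 1, 1, 1.99,
2.01 with 20 Gaussian points each (sd 0.15 by default; the gap design
plants a structural triad A–B–C that should appear as one branch, with D
and E separate).  `twoMoons()` interlocks a 200-degree "gibbous" arc with
a 140-degree offset "crescent" arc (1000 points per moon by default,
isotropic noise 0.05).  `blockSimilarity()` plants exact block structure
with optional jitter, clipped to $[10^{-12}, 1]$ so no node is fully
disconnected.  All generators are bit-reproducible given a seed.

What these fixtures do *not* emulate: heteroscedastic noise, missing
entries, non-metric similarities, and the size and correlation structure
of real relational data (brain connectivity, expression profiles).
Passing the benchmark suite shows the machinery resolves planted
multi-scale geometry at desk scale; it does not certify performance on
any particular real data set.

## Numerical choices and degenerate inputs

* Diagonal similarity is ignored (weight 0, no self-transitions).
* Nodes with zero similarity to all others never join a walk and are
  emitted as their own co-well segments; a scan aborts with a diagnostic
  if the cluster count cannot reach 1 + (number of isolated nodes) even
  after grid extension.
* At very low temperature, cross-well weights underflow to exactly 0; a
  chain stranded without positive-weight neighbors restarts uniformly
  among the remaining nodes (counted and reported in the `WalkRecord`).
* Per-evaluation and per-walk seeds are derived from the master seed with
  a fixed 31-bit linear mix in evaluation order, making scans, trees and
  every written artifact byte-reproducible; the walk's inner loop uses its
  own Mersenne Twister stream, independent of R's RNG state.
* Equality comparisons against level temperatures use a relative
  tolerance of $10^{-12}$; ties in the Parisi child ordering break by
  smallest member index.

## Problem sizes used by the validation suite

The test suite exercises the pipeline at sizes a laptop handles in
minutes: the two-moons benchmark runs at 200 points per moon over 5 master
seeds, five-dots at its design size $N = 100$ over 20 replicates
(sd swept over 0.1, 0.15, 0.2), and planted-block recovery at $N = 22$
over 20 seeds.  The walk engine itself is linear in $N m$ steps of $O(N)$
work, so a full 24-temperature scan of a 400-node cloud with $E = 50$
takes on the order of a minute.

## Known limitations

* With the exponential distance transform, elongated chain-like clusters
  (each moon's arc) have end-to-end link energies far larger than the
  cross-cluster gap; at the temperature where a whole arc becomes
  traversable the gap is crossed too, so the two-cluster level of the
  scaled-down moons benchmark is detected as a count but its membership
  is not moon-pure.  Resolving chains would need a locality-sharpening
  similarity (for example a squared-exponential kernel with a local
  scale), which is outside the present input contract.
* The cap rule's stranded-node effect (above) keeps strict block
  contiguity of removal orders at roughly 70–75% on deep two-block
  landscapes; segment quality is recovered by the ensemble average.
* "Major level" is formalized as a plateau covering at least `plateauMin`
  refined grid points; on smooth staircases (many narrow, genuine phases)
  this keeps most levels, and no small fixed number of "major" levels
  should be expected.
* The single-cluster level inherits the top of the (extended) grid as its
  height; root heights are therefore comparable between runs only for
  equal grids.
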