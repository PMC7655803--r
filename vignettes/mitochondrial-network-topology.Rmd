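---
title: "Quantifying mitochondria interaction network topology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitochondria interaction network topology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitotopo)
```

## The model

Mitochondria inside a cell form physically connected structures that can be
read out of 3D fluorescence image stacks. After segmentation and
skeletonization, the structure is a one-voxel-thick curve skeleton; its
branch points and endpoints (voxels with a 26-neighbour count different
from 2) become the nodes of a *mitochondria interaction network* (MIN), and
the chains of degree-2 voxels between them become links. The adjacency
matrix is the weighted variant in which `A[i, j]` holds the voxel count of
the link; any `A[i, j] > 0` counts as a link for all topological analyses,
so link weights carry image fidelity but never affect the metrics.

A MIN is typically disconnected. The unit of analysis is therefore the
connected component ("subnetwork"), whose node count is the size `s`. Per
component the package computes: normalized degrees `k* = k/N`, link density,
max degree, ASPL (mean geodesic distance over ordered pairs), diameter,
efficiency (mean reciprocal geodesic distance), Louvain modularity,
degree assortativity, transitivity, an information-content measure, a small
worldness ratio, and the census of induced 3-/4-node connected motifs.

Raw metric values are incomparable across components of different sizes and
densities, so each is normalized as a Z-score against a null ensemble of
100 connected random graphs with exactly the component's node and link
counts, `z = (M - mean(M_rand)) / sd(M_rand)`. Ensembles whose SD is zero
(e.g. a complete graph admits only one graph) yield an explicit undefined
flag rather than an infinite Z.

Finally, three cohort-level analyses sit on top: (1) the cumulative
component-size distribution `P(s)` is fitted as the decay `P(s) = a k^s`
and group slopes are compared; (2) per-metric Z-score distributions are
compared between groups with two-sample two-sided Kolmogorov–Smirnov tests
under a Šidák-corrected family threshold, and per-subject feature means are
correlated with the UPDRS clinical score; (3) subjects are classified
(PD vs control) from per-component Z-score features by a multilayer
perceptron under leave-one-subject-out cross-validation (LOSO-CV) with a
50-fold label-reshuffling control.

## Choices at points the procedure leaves open

Several steps are under-determined by their usual textbook description;
the package fixes them as follows.

**Null model.** Random graphs are uniform draws from `G(n, l)` conditioned
on connectivity (rejection sampling, cap 10^4, then a spanning-tree-plus-
random-links fallback flagged `biased`). Degree sequences are *not*
preserved; only node and link counts are matched. This materially changes
Z magnitudes relative to degree-preserving rewiring and is the literal
reading of "same number of nodes and links, single component".

**Link-weight convention.** A link's voxel count includes both terminal
node voxels, so every link has weight at least 2; two directly adjacent
branch voxels form a weight-2 link. Parallel voxel paths between the same
node pair are collapsed by summing counts (an adjacency matrix cannot hold
multi-edges), and paths returning to their own origin are dropped.

**Degree-2 vertices and rasterization.** Under the branch-point rule a
degree-2 vertex is indistinguishable from link interior, so the class of
graphs a skeleton can encode has no degree-2 vertices. `smooth_network()`
reduces any component to that class (merging link weights with the shared
voxel counted once), and `rasterize_to_skeleton()` embeds such graphs in a
voxel grid with collision-free routing (private slabs per link, corner-cut
turns, attachment slots capped at degree 8). Round-trip tests assert that
extraction recovers the embedded graph and its recorded voxel counts
exactly.

**Thinning.** `skeletonize_mask()` performs sequential topology-preserving
thinning: border voxels that are simple points under Bertrand's
characterization (one foreground 26-component in the neighbourhood, one
center-adjacent background 6-component in the 18-neighbourhood) and not
curve endpoints are removed in directional passes until stability.
Foreground 26-connectivity was chosen to match common 3D skeleton tooling;
the alternative 6-connectivity reading would split diagonal contacts.

**Information content.** The mesoscale-regularity measure is
operationalized as a greedy agglomeration: at each of the `s - 1` steps,
merge the node pair whose adjacency rows disagree on the fewest other
nodes, at a cost of `log2(choose(n - 2, m))` bits (the information needed
to localize the `m` disagreeing entries); ties break toward the lowest node
ids, and the merged row is the elementwise OR. The total accumulated bits
is the reported value. This fixed, documented variant is tested for its own
invariants (0 for complete graphs and identical-neighbourhood merges,
positive mean on Erdős–Rényi graphs); it is not claimed to equal any
specific published variant numerically.

**Size-distribution fit.** The fit runs on the cumulative curve (as such
curves are conventionally displayed), by Levenberg–Marquardt least squares,
after dropping the lowest and highest 10% of *distinct* sizes. The model is
exponential in `s` exactly as written (`a k^s`); a strict power law
`a s^(-gamma)` is available via `model = "power"` for sensitivity checks.
The slope-comparison test represents each slope as a normal variable with
SD equal to the 68% CI half-width (the full-width reading is available via
`sd_rule = "full"`).

**The 68% CI of the slope.** The asymptotic covariance of the
least-squares fit treats the cumulative points as independent observations,
but every point shares the same underlying components; on sampled cohorts
that CI understates the sampling variability of `k` several-fold and makes
the slope test wildly anticonservative (measured type-I error about 65% at
nominal 5%). `fit_slope()` therefore computes the 68% CI by a
component-resampling bootstrap (default 100 replicates) whenever raw sizes
are supplied, which restores calibration (measured 8% over 200 same-slope
pairs); the covariance CI remains available (`ci_method = "covariance"`)
and is used automatically for curve-only input such as noiseless analytic
checks.

**K-S p-values.** Exact two-sample p-values are used when both samples have
at most 25 observations, the asymptotic approximation above that. At pooled
per-component sample sizes (hundreds of components) the asymptotic null
p-values are close to uniform; at small n the exact test is discrete and
conservative.

**Clinical correlation.** The per-subject value is the mean of the metric
over that subject's components of the configured size; subjects lacking
such components are dropped. On synthetic cohorts the size is chosen as the
largest size present in at least three PD subjects, mirroring the
requirement that the size exist across individuals.

**Classification.** Instances are components, not subject aggregates —
each subject contributes many networks, which is exactly why the
cross-validation must hold out entire subjects. The model is a single
hidden-layer perceptron (`nnet`), default 16 hidden units, logistic output,
weight decay 0.01, at most 500 epochs, seeded per fold; features are
standardized and median-imputed with training-fold statistics only;
instances with more than half their features undefined are dropped. ROC
curves are pooled across folds and AUC uses the trapezoidal rule, which is
identical to the midrank Mann–Whitney normalization under ties. Label
reshuffles permute the subject-to-label map, so all of a subject's
instances move together.

**Motif naming.** The "paw-like" 4-node motif is mapped to the triangle
with a pendant edge (`p4_paw`) and the "U-shape" to the 4-path
(`p4_path`). These figure-only names cannot be pinned down from text; the
census reports all six connected 4-node classes, so any remapping is a
column choice, not a recomputation.

## The synthetic cohort generator

The study's raw data are hundreds of gigabytes of 3D image stacks, so the
package ships a generator that emulates the statistical structure the
analysis relies on, at desk scale:

- **Sizes** are drawn from the discrete truncated distribution
  `p(s) proportional to k^s` on `[min_size, max_size]` — the discrete
  counterpart of the fitted decay, with explicit truncation because real
  cohorts trim tails rather than model them. Defaults: `k = 0.75` (PD) vs
  `0.65` (control) on sizes 2–28, giving the PD group its excess of larger
  components; 28 is the largest size retained by the component-size
  restriction rule (sizes >= 29 are excluded as too rare).
- **Wiring** starts from a spanning structure interpolating between a
  random tree and a path: nodes are visited in random order and each
  attaches to its predecessor with probability `chain_bias`, else to a
  uniform earlier node. High chain bias (PD default 0.8 vs control 0.4)
  produces path-like components with larger ASPL and diameter and lower
  efficiency. Extra links (binomial, mean 0.15 per node) close a random
  open triad with probability `triangle_propensity` (PD 0.6 vs control
  0.3), steering transitivity and triangle-motif counts. The three knobs
  steer the three metric families (size, triangles, path lengths) roughly
  independently; the per-group directions emulate the reported group
  contrasts qualitatively, not their magnitudes, which are not recoverable
  at this scale.
- **Subjects** get a wiring jitter (SD 0.05 on chain bias) and, for PD, a
  synthetic UPDRS score increasing with that jitter, so lower-efficiency
  subjects score higher — the direction of the reported clinical
  correlation. With only four PD subjects the estimated correlation is
  sign-unstable; the analysis scripts report it as computed.
- **Weights** are uniform integers in \[2, 20\]; they never affect
  topology metrics.

What the generator does *not* emulate: fluorescence, staining noise,
segmentation errors, spatial embedding of components within a ganglion,
within-subject correlation structure beyond the single wiring jitter, and
any absolute effect magnitudes. Passing tests on this cohort demonstrate
that the pipeline measures what it claims on data with the assumed
structure — not that real images would reproduce the reported effect
sizes.

## Problem sizes and runtime choices

The default cohort is 4 + 4 subjects with 200 components each (1600
components, sizes 2–28), which exercises every stage in a few minutes.
Null ensembles hold 100 graphs; because ensemble membership depends only on
the (nodes, links) pair, `zscores_table()` caches one ensemble per pair and
reuses it across components — a pure efficiency measure that does not
change any distribution. Test-suite calibrations use 200 same-slope pairs
of 5000-component cohorts for the slope test, 100 replicates for slope
recovery, 100 round-trip embeddings, 50 components of fresh null draws for
Z self-consistency, and 50 label reshuffles for the classification
control; the analysis drivers use a hidden layer of 8 units and 200 epochs
to keep 400+ LOSO fits quick.

## Known limitations

- Components are pooled across networks and subjects in group tests; no
  mixed-effects handling of within-subject correlation.
- The connected-`G(n, l)` fallback sampler (after 10^4 rejections) is not
  exactly uniform; it is flagged and practically reached only for sparse
  large components.
- The rasterizer handles degrees up to 8 (its attachment-slot geometry);
  the thinning routine is sequential and intended for fixture-scale
  volumes, not whole-image stacks.
- `skeletonize_mask` preserves topology but, like all thinning, does not
  guarantee a unique or centered skeleton; extraction assumes a clean
  one-voxel skeleton and raises an error on ambiguous tracing.
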