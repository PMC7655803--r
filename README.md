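# mitotopo

Topological analysis of mitochondria interaction networks (MINs).

Mitochondria form physically connected structures whose skeletons, extracted
from 3D fluorescence image stacks, define graphs: branch points are nodes,
voxel chains between them are weighted links (`A[i,j]` = voxel count of the
link, any positive entry counts as a link). Those graphs decompose into
thousands of small connected components per sample. This package implements
the full analysis chain used to compare such networks between subject groups
(e.g. Parkinson's disease patients vs healthy controls):

- **Skeleton → network**: topology-preserving 3D thinning
  (`skeletonize_mask`), branch-point tracing with the THR = 0 convention
  (`skeleton_to_network`), TIFF stack I/O, plus a voxel rasterizer
  (`rasterize_to_skeleton`) that embeds graphs back into volumes for
  round-trip validation.
- **Per-component metrics**: normalized degree `k* = k/N`, link density,
  max degree, ASPL, diameter, efficiency (harmonic mean of geodesic
  distances), Louvain modularity, degree assortativity, transitivity,
  information content, small worldness, and the induced 3-/4-node motif
  census (V-shape, triangle; path, star, paw, cycle, diamond, K4).
- **Null-model normalization**: per component, 100 connected random graphs
  with matched node and link counts; every metric and motif count becomes a
  Z-score `(M - mean(M_rand)) / sd(M_rand)`, with explicit undefined flags
  when the null SD is zero.
- **Size distributions**: cumulative `P(s)` fitted as the decay
  `P(s) = a·k^s` (Levenberg–Marquardt, 10% tail trimming) and a slope
  comparison test between groups.
- **Group statistics**: two-sample two-sided Kolmogorov–Smirnov tests with
  Šidák correction, subsampling stability reports, and Pearson correlation
  of per-subject features with UPDRS clinical scores.
- **Classification**: multilayer-perceptron classification of PD vs control
  under leave-one-subject-out cross-validation (no subject ever scores
  itself), pooled ROC/AUC, and a 50× subject-level label-reshuffling
  control.
- **Synthetic cohorts**: a generator (`cohort_spec`, `generate_cohort`)
  producing subject-labelled cohorts with group-dependent size slope,
  triangle propensity and chain-like wiring, so the entire pipeline is
  testable without the (non-desk-scale) raw image data.

## Worked example

The `analysis/` directory holds the numbered drivers of the full workflow;
run them in order from the repository root:

```sh
Rscript analysis/01_simulate_cohort.R     # cohort -> results/cohort/
Rscript analysis/02_component_metrics.R   # per-component metric table
Rscript analysis/03_null_zscores.R        # 100-graph null Z-scores
Rscript analysis/04_size_distribution.R   # P(s) ~ k^s fits + slope test
Rscript analysis/05_group_statistics.R    # K-S family, stability, UPDRS
Rscript analysis/06_classification.R      # LOSO-CV + reshuffle control
```

With the default conditions (4 PD + 4 control subjects, 200 components
each, PD slope 0.75 vs control 0.65, PD wiring more chain-like and more
triangle-closing), the drivers print:

```
Computed metrics for 1600 components (sizes 2..24)
  PD       mean size 4.93, mean efficiency 0.777, mean ASPL 1.699, mean transitivity 0.200
  control  mean size 3.84, mean efficiency 0.844, mean ASPL 1.403, mean transitivity 0.150

control  k = 0.6631 +/- 0.0118 (68% CI), support s in [3, 18], 800 components
PD       k = 0.7463 +/- 0.0092 (68% CI), support s in [3, 20], 800 components
Slope comparison PD vs control: z = 5.55, p = 2.9e-08

LOSO-CV AUC: 0.608 over 390 instances, 8 folds
Reshuffled-label AUC: mean 0.383, 95th percentile 0.483 over 50 permutations
```

Reading the numbers: the fitted slopes recover the generating values
(0.75 / 0.65) within their bootstrap CIs, and the slope test rejects the
shared-slope null decisively — the PD group's components are systematically
larger. PD components are also less efficient and longer-pathed (the chain
bias), which the Kolmogorov–Smirnov family flags on the Z-score
distributions after Šidák correction. The component-level LOSO-CV AUC is
modest at these desk-scale effect sizes — the point of the control is that
it collapses further under label reshuffling, showing the real labels carry
signal that permuted labels do not.

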