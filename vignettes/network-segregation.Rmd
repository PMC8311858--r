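---
title: "Measuring network segregation of a stimulated brain region"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring network segregation of a stimulated brain region}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Resting-state fMRI connectomes organize into modules — groups of regions
whose spontaneous signals are tightly correlated. A region is *segregated*
when its connections stay inside its own module, and acts as a *connector
hub* when they spread across many modules. In neurodegenerative disease the
balance can shift: a damaged region may become abnormally coupled to
systems outside its own, and an intervention (here, transcranial
direct-current stimulation, tDCS, applied over the left inferior frontal
gyrus during language therapy) may push it back. `connseg` implements the
full analysis chain for asking such questions with node-level statistics,
and a synthetic-cohort generator that makes every stage testable against
planted ground truth.

## The measure

All analyses revolve around the participation coefficient of a node $i$ in
a binary graph with a fixed modular partition of $M$ modules:

$$\mathrm{PC}_i \;=\; 1 - \sum_{m=1}^{M} \left(\frac{k_i(m)}{k_i}\right)^{2},$$

where $k_i$ is the node's degree and $k_i(m)$ its number of edges into
module $m$. $\mathrm{PC}_i = 0$ when every edge stays in one module and
approaches $1 - 1/M$ as edges spread evenly over all modules. Isolated
nodes ($k_i = 0$) are assigned 0 — the "no diversity" reading — so sparse
graphs never produce undefined values. Alongside PC, the package reports
the raw material behind it: mean numbers of within-module, between-module,
per-module and per-hemisphere connections.

## The pipeline

1. **Connectivity** (`fisher_z_connectivity`). Pairwise Pearson
   correlations between ROI time courses, Fisher z-transformed
   (`atanh`). Values are capped at `atanh(1 - 1e-7)` so that perfectly
   correlated signals (possible in synthetic data) stay finite. Constant
   signals make the correlation undefined and raise an error naming the
   ROI.
2. **Binarization** (`multi_threshold_graphs`). Proportional thresholding:
   at proportion $p$ exactly $\mathrm{round}(p\,n(n-1)/2)$ edges with the
   largest *signed* z-values are kept. The defaults are the six
   proportions 5, 10, 20, 25, 30 and 40%. Because no agreed cut-off
   exists, every node metric is computed at each threshold and averaged
   with equal weights; per-threshold values remain available.
3. **Reference modules** (`ward_partition`). The modular partition is
   derived once from the healthy-control group-mean matrix by
   agglomerative clustering with Ward's criterion and then frozen: every
   subject and timepoint is scored against the same organization, because
   PC values are only comparable against a common partition. The packaged
   reference organization (`reference_partition()`) has seven bilateral
   modules (perisylvian, temporal, frontoparietal, dorsal frontoparietal,
   ventromedial prefrontal, occipital-temporal, subcortical) over a
   76-node, 38-per-hemisphere node table, with the stimulation target
   `LIFG_tri` in the perisylvian module. Its per-node memberships are a
   synthetic stand-in constructed for this package; the module count and
   bilateral structure are what analyses rely on.
4. **Node metrics** (`compute_node_metrics`). Threshold-averaged PC and
   connection counts for the stimulation target and four control ROIs
   (right-hemisphere homolog, right precuneus, and the two other left
   inferior frontal subdivisions).
5. **Statistics** (`pretreatment_model`, `change_model`,
   `paired_change_test`, `independent_group_test`,
   `brain_behavior_model`, `per_module_tests`). Ordinary linear models and
   classical t tests; see below.

## Numerical choices

Several details are fixed so that results are bit-reproducible and
documented rather than implementation accidents:

* **Edge-count rounding** is round-half-away-from-zero: at $p = 0.05$ on
  76 nodes, $0.05 \times 2850 = 142.5$ keeps 143 edges. (R's `round()`
  rounds half to even and would keep 142.)
* **Ranking is by signed value.** A strongly negative correlation is never
  among the "strongest connections". An absolute-value variant is
  deliberately out of scope.
* **Ties** in the ranking are broken by ascending $(i, j)$ node order.
  Real-valued data essentially never ties, but toy fixtures do, and the
  selection must be deterministic.
* **Ward features.** Each node's feature vector for clustering is its row
  of the group-mean Fisher-z matrix with the diagonal entry set to 0, with
  Euclidean inter-row distances and `ward.D2` linkage. This is the most
  literal reading of clustering "the averaged correlation matrix";
  supplying $1-r$ as a precomputed distance is incompatible with exact
  Ward updates.
* **The number of modules `k` is a design input**, default 7. No selection
  criterion is pretended; `silhouette_profile()` reports mean silhouette
  widths over candidate `k` as guidance only.
* **Factor coding** in models: gender reference `F`, treatment arm
  reference `sham`, cohort reference `HC`. Group-vs-control t tests use
  pooled variance (so `df = n1 + n2 - 2`, the convention of the field's
  reports); Welch is available behind a flag. p-values for the per-module
  between-module comparisons are Benjamini–Hochberg adjusted within each
  comparison family; the primary target-node tests are not corrected.

## The synthetic cohort generator

`cohort_design()` + `simulate_cohort()` generate a longitudinal cohort
with known ground truth:

* A planted bilateral partition (default: the packaged seven-module
  organization).
* Block-structured correlations: `within_r = 0.5` inside modules,
  `between_r = 0.1` across. These produce clearly modular but not trivial
  structure; Ward clustering recovers the planted modules from
  19 simulated controls at scan length 210 essentially always.
* One target node (`LIFG_tri`) whose between-module correlation is
  elevated by `severity_slope` (default 0.02) per unit of a 0–15 dementia
  severity score, drawn uniformly on a 0.5 grid between 1 and 15.
* An active-arm-only mean reduction `treatment_effect` (default 0.15) of
  that elevation at the post timepoint, with between-subject SD
  `effect_sd` (default 0.05) in both arms (the sham arm drifts around
  zero), which gives subjects individual neural-change magnitudes so that
  brain–behavior relationships are estimable.
* Group sizes 19 controls (one scan) and 16 patients per arm (pre and
  post), scan length `t_len = 210` time points, with an option for a
  cohort mixing 210 and 156 to emulate pooled acquisition protocols.
* Behavioral gain (percent of maximal improvement, 0–100) generated so
  that larger realized reductions pay off in the active arm, severity
  costs improvement, and the sham arm's drift correlates positively with
  gain. These coefficients are free parameters of the generator — nothing
  in the clinical literature pins them — and are exercised by the tests
  only through their signs.

Sampled covariances must stay positive semi-definite. Perturbations can
break this, so matrices are repaired by clipping negative eigenvalues,
re-symmetrizing and rescaling to unit diagonal; generation *errors* if the
repair would move any entry by more than `max_psd_drift` (default 0.05),
so a repair can never silently erase the planted contrast. The realized
per-subject elevation is additionally capped at `bump_cap` (default 0.32),
the edge of the region where repair stays within that bound.

Seeding is hierarchical: one base seed fans out to per-subject substreams
(subject-index offsets), so adding a subject to a design never changes any
other subject's data, and regeneration is bit-identical.

### What the generator does and does not emulate

It reproduces the *statistical skeleton* the analysis assumes:
block-modular correlations, a severity-scaled hub perturbation, an
arm-specific longitudinal change, and the covariate structure of the
clinical design. It does not emulate hemodynamic autocorrelation, spatial
smoothness, atrophy, head motion (motion enters only as a covariate
value), or heterogeneous edge weights within blocks. Passing tests
therefore demonstrate that the pipeline recovers what it claims to measure
under its own model assumptions — not that those assumptions hold in any
given clinical data set.

One consequence of the idealized two-level block structure is worth
knowing: because thresholding is rank-based and all of the target's
between-module correlations move together, the target's retained-edge
count responds to the planted elevation as a fairly sharp step once the
elevation exceeds correlation sampling noise ($\approx 1/\sqrt{T}$). At
very long scans the PC–severity response therefore saturates early in the
severity range, while at the default `t_len = 210` it is graded across the
full range. The package's validation battery consequently runs its
effect-recovery study at the default design (scan length 210,
`severity_slope = 0.02`, `treatment_effect = 0.15`), where every planted
effect is detected in well over 80% of replicates; type-I calibration uses
null cohorts (all planted effects zero) at a reduced scan length of 60,
500 replicates, where each model's rejection rate sits at the nominal 5%.
Recovery of the planted modules is checked over 20 cohorts of 19 controls
at scan length 210.

## Worked example

```{r example}
library(connseg)

design <- cohort_design(seed = 1)
report <- run_pipeline(pipeline_config(design = design, seed = 1))
report

# severity association of the target's PC before treatment
tidy(report$stats$LIFG_tri$pretreatment)

# treatment-arm contrast on post-minus-pre PC
tidy(report$stats$LIFG_tri$change)

# per-module between-module comparisons, BH-adjusted
report$per_module

# displays
plot_pc_change(report$metrics, simulate_cohort(design)$covariates)
```

## Known limitations

* The reference organization's node memberships are synthetic; analyses of
  real data should supply their own partition file
  (`load_reference_partition()`), derived from their own controls.
* Effect sizes in the generator are free parameters, not calibrated to
  clinical data; power statements transfer to real data only insofar as
  the block model approximates it.
* The pipeline starts at ROI time series. Image preprocessing,
  parcellation and motion estimation are upstream concerns and out of
  scope, as are modularity-maximization community detection, per-subject
  partitions, weighted-graph variants, and centrality measures other than
  the participation coefficient.
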