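---
title: "Methods: graph-theoretical group comparison of functional brain networks"
author: "connectograph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-theoretical group comparison of functional brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`connectograph` implements a complete resting-state functional-connectome
comparison pipeline for a three-group design — patients with familial
schizophrenia (PFS), patients with sporadic schizophrenia (PSS), and healthy
controls (HC):

1. **Preprocessing** of regional (ROI) time series: discard of initial
   volumes, frame-wise displacement (FD) and spike flagging, nuisance
   regression, band-pass filtering.
2. **Network construction**: per-subject Pearson correlation matrices,
   binarized at an exact edge count over a sweep of sparsity thresholds.
3. **Graph metrics**: clustering coefficient $C_p$, characteristic path
   length $L_p$, global and local efficiency $E_{glob}$, $E_{loc}$, and the
   normalized indices $\gamma = C_p / C_p^{rand}$,
   $\lambda = L_p / L_p^{rand}$, $\sigma = \gamma / \lambda$ against
   degree-preserving random references; nodal degree, betweenness and
   efficiency; area-under-curve (AUC) summaries over the sparsity grid.
4. **Inference**: one-way ANOVA on every AUC metric with pairwise
   follow-ups, node screening, network-based statistics (NBS) on edges with
   a max-component-size permutation null, and covariate-adjusted partial
   correlations between significant metrics and PANSS symptom scores.
5. A **synthetic cohort generator** that plants known group effects, so
   every stage can be validated against ground truth.

Because no subject-level imaging data are distributed, the synthetic
generator is a first-class component: it defines the study conditions under
which the pipeline is exercised and validated.

# The synthetic cohort model

Each subject's regional signal is drawn from a zero-mean multivariate
normal whose correlation matrix is **block-modular**: `nModules` contiguous
blocks of regions with within-module correlation `withinModuleR` and
between-module correlation `betweenModuleR`. On top of this baseline the
generator plants:

* **Edge-strength deficits** — two disjoint connected circuits of node
  pairs, one per patient group (by default 13 edges / 13 nodes for the
  PFS analogue, 12 edges / 12 nodes for the PSS analogue, mirroring the
  reported component sizes), whose target correlations are reduced by
  `deficitEffect`.
* A **clustering (randomization) shift** — the within-module correlation of
  one patient group (default PFS) is scaled down by the fraction
  `clusteringShift`, moving its networks toward random topology: lower
  $\gamma$, $\sigma$ and $E_{loc}$ with little change in $\lambda$ and
  $E_{glob}$.
* A **subject-level severity multiplier** (truncated normal, mean 1, sd
  `severitySd`) that scales both planted effects for each patient, and a
  **symptom link**: the PANSS negative subscale is
  `20 + symptomLink * (severity - 1) + noise`, clipped to the legal
  subscale range [7, 49]. This gives the partial-correlation stage a
  recoverable association of known sign.
* **Motion**: a low-amplitude random-walk drift on all six rigid-body
  parameters plus one-volume x-translation excursions of 0.6–1.5 mm at
  Bernoulli(`spikeRate`) volumes, each exceeding the 0.5 mm FD threshold by
  construction; spike volumes also receive a motion-coupled signal offset
  (`spikeArtifact` per mm) that the spike regressors can absorb.
* Slow sinusoidal scanner drift (0.005 Hz), removed by the band-pass.

After planting, the target matrix is projected to the nearest positive
semi-definite correlation matrix by eigenvalue clipping and
re-normalization to unit diagonal; this is simple, reproducible, and
preserves the sign of planted effects. Target entries outside $[-1, 1]$ are
rejected with a diagnostic naming the offending edges.

**Default effect sizes are generator choices, not reported values.** The
emulated study reports which groups differ but not the magnitude of
connectivity reduction, so the defaults were fixed once at values a
simulation study in this field would call a strong planted effect:
`withinModuleR = 0.40` and `betweenModuleR = 0.08` give clearly modular but
realistic correlation levels for band-pass-filtered regional signals;
`deficitEffect = 0.25` is a large fraction of the within-module baseline;
`clusteringShift = 0.30` removes about a third of the modular contrast;
`severitySd = 0.25`, `symptomLink = 24` and `symptomNoiseSd = 3` make the
severity-to-symptom correlation strong while leaving the
severity-to-measured-metric channel realistically noisy. Cohort layout
defaults (3 × 26 subjects, 90 regions, 180 volumes of which 10 are
discarded, TR = 2 s) mirror the emulated design; ages are drawn from
Normal(32.5, 7) and sex is balanced 13/13 within groups so the groups are
matched on both covariates by construction.

**Reproducibility.** One master integer seed feeds a named sub-stream per
subject and stage (a hash of `"series:<id>"`, `"motion:<id>"`, …), so the
same seed reproduces the same cohort bit-for-bit and per-subject data do
not depend on cohort size or evaluation order.

# Preprocessing

The stage order is fixed: discard → FD/spike flagging → nuisance regression
(with spike indicator columns) → band-pass. The source study states the
steps but not the order of spike regression relative to filtering; the
order above regresses spikes first so the indicator columns can absorb
artifact volumes exactly, a documented package choice.

* **FD** uses the Power convention: the sum over the six parameters of the
  absolute backward difference, with rotations converted to arc length on a
  50 mm sphere. `fd[1] = 0`; volumes with FD *strictly greater* than 0.5 mm
  are flagged.
* **Nuisance regression** is ordinary least squares against intercept,
  linear trend, the six motion parameters, their first differences (row 1
  backfilled with 0), optionally the global signal (mean over regions), and
  one indicator per flagged volume. White-matter and CSF signals are
  accepted as extra confound columns when available; the synthetic
  generator produces no voxel data, so they are omitted by default.
  Collinear columns are dropped with a warning. Residuals are exactly
  orthogonal to the retained design.
* **Band-pass** is a zero-phase forward-backward 4th-order Butterworth
  (0.01–0.08 Hz), the standard choice in resting-state work; the band edges
  are the only values the emulated study states. All regions are filtered
  in one matrix pass that is numerically identical to column-wise
  `signal::filtfilt`.
* Global-signal regression (GSR) is controversial, so the pipeline runs
  **both** GSR and no-GSR variants side by side, keyed identically in the
  report.

# Network construction

Pearson correlations between all region pairs give a symmetric matrix with
the diagonal set to 0. Binarization retains **exactly**
$K = \mathrm{round}(s \cdot N(N-1)/2)$ edges at sparsity $s$ — the $K$
pairs with the largest $|r|$ (negative correlations can become edges) — so
all subjects' networks have the same edge count and group comparisons see
relative organization only. $K$ rounds half away from zero and ties at the
cutoff break by lowest lexicographic pair index, making the output
deterministic across platforms; both conventions are package choices where
the source is silent. Because the retained set is a prefix of one ranking,
edge sets are nested along the default grid $s = 0.10, 0.11, \dots, 0.34$.

# Graph metrics and normalization

All metrics operate on the binary graphs. $L_p$ averages hop distances over
*reachable* pairs only, keeping it finite when low-sparsity networks
fragment (efficiencies need no convention since $1/\infty = 0$); local
efficiency of a node is the global efficiency of its open neighbourhood
subgraph, 0 for degree < 2; regional "efficiency" is read as nodal
(closeness-type) efficiency, the standard interpretation. Betweenness is
unnormalized Brandes betweenness — only relative group differences matter.

Random references are generated by **degree-preserving double-edge swaps**
(Maslov–Sneppen; 10 attempted swaps per edge, 100 references by default —
conventions, since the original toolbox settings are unreported, and both
configurable). $\gamma$, $\lambda$, $\sigma$ divide by the mean $C_p$ and
$L_p$ of the references. Inside the sparsity sweep the references' $C_p$
and $L_p$ are computed through igraph's C routines, which the test suite
verifies to be exactly this package's conventions and exactly the graphs
the exported `randomReference()` returns under the same seed.

Every metric curve is summarised by its trapezoidal AUC over the grid, a
threshold-independent scalar.

# Inference

* **ANOVA**: classical equal-variance one-way F on each AUC metric, with
  pooled-variance two-sample t follow-ups computed only when the omnibus
  p < 0.05. Nodal ANOVAs are deliberately uncorrected (a node-screening,
  exploratory stage); Bonferroni/FDR can be applied by the user to the
  returned p-value tables.
* **Node screening**: a node enters the NBS stage when any of its three
  nodal-metric AUCs shows an omnibus p < 0.05.
* **NBS**: pairwise pooled-variance t statistics on Fisher z-transformed
  edge values (a raw-r mode is available), thresholded at |t| > 2.0;
  suprathreshold components are scored by edge count ("extent") and
  referred to a max-component-size null from label permutations
  (default 10000). The corrected p is
  $(1 + \#\{\text{perm max} \ge s\})/(n_{perm} + 1)$, which cannot be zero;
  when fewer distinct label assignments exist than requested permutations
  the null is enumerated exhaustively. Pairwise t (not a three-group F) is
  used because the emulated analysis reports pair-specific circuits at a
  threshold of 2.0, a t-scale value; edge count is NBS's default extent
  measure. Both are documented interpretations of an underspecified source.
* **Partial correlation**: Pearson correlation of least-squares residuals
  after regressing out intercept + covariates (age, sex as a 0/1
  indicator), p from the t transform with $df = n - 2 - k$.

# Validation design and problem sizes

The test suite validates every operation against independent oracles
(Floyd–Warshall distances, exhaustive shortest-path enumeration for
betweenness, neighbour-pair triangle counting, hand-evaluated closed
forms) and then exercises the whole pipeline on synthetic ground truth.
The simulation-scale checks use these package-chosen desk scales:

* small-world recovery: the full default cohort (78 subjects, 90 regions,
  25 thresholds) with 20 random references per network;
* NBS error control: 200 null cohorts of 13 subjects per group and 30
  regions at 1000 permutations;
* NBS recovery: 50 cohorts at the default effect with 30 regions;
* clustering-shift detection: 50 cohorts with 60 regions, a 4-point grid
  and 3 references. Sixty regions keep the modules at 10 regions; with
  5-region modules (30 regions) binarized networks carry almost no modular
  clustering signal and the shift is undetectable by any measurement — a
  property of network size, not effect size. The shift factor is tested in
  isolation (edge deficits off) because the other group's planted deficit
  circuit would otherwise leak into its own local-efficiency curve and
  confound the "unaffected group" control;
* symptom-link recovery: 50 cohorts at the full 90-region default, with a
  3-point grid and 4 references, correlating each PFS subject's
  $\gamma$ AUC with the PANSS negative score (age/sex adjusted).

What passing these checks shows — and what it does not: the generator's
multivariate-normal signals have no hemodynamic convolution, no
physiological noise spectra, no spatial structure beyond block modularity,
and motion that corrupts the signal only through additive spike offsets.
Recovery on this ground truth demonstrates that the pipeline's statistics
do what they claim under the stated model; it cannot certify performance on
real scanner data.

# Known limitations

* Binary networks only; weighted-network analysis is out of scope.
* $L_p$'s reachable-pairs convention makes it insensitive to fragment
  counts; compare $E_{glob}$ when fragmentation matters.
* The permutation null assumes exchangeability of subjects across the two
  compared groups (no covariate-adjusted NBS).
* The severity-to-metric channel is intentionally noisy; subject-level
  metric estimates at 170 retained volumes carry substantial sampling
  noise, which bounds attainable symptom correlations well below the
  planted severity–symptom correlation.

# A minimal run

```{r, eval = FALSE}
library(connectograph)
cfg <- cohortConfig(nPerGroup = 10, nRois = 30, seed = 1)
res <- runPipeline(cfg, grid = c(0.10, 0.22, 0.34), nRandom = 10,
                   nPermutations = 1000, outDir = "report")
res$gsr$anovaGlobal
```
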