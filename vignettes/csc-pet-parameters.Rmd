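---
title: "Measuring cancer-stem-cell metabolism from FDG-PET SUV histograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cancer-stem-cell metabolism from FDG-PET SUV histograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petcsc)
```

## The model

A tumor is metabolically heterogeneous: proliferative cancer stem cells
(CSCs) run a strongly glycolytic program, differentiated cancer cells lean
on oxidative phosphorylation, and — at PET's 4-mm spatial resolution — many
voxels contain a mixture of both. Since FDG uptake images glycolysis (the
Warburg effect), the standardized-uptake-value (SUV) histogram of a lesion
should decompose into three populations ordered by uptake: differentiated,
mixed, and CSC-dominated voxels.

`petcsc` operationalises this as a three-stage measurement:

1. the lesion volume of interest (VOI) is the 26-connected set of voxels
   with SUV ≥ 2.5 around a user (or generator) supplied seed voxel;
2. the VOI's voxel SUVs are partitioned into $K = 3$ clusters minimising
   the within-cluster sum of squares (WCSS);
3. the highest-centroid cluster $C_2$ is read as the CSC compartment, giving
   $\mathrm{MTV_{csc}} = |C_2| \cdot v$, $\mathrm{TLG_{csc}} =
   v \sum_{x \in C_2} \mathrm{SUV}(x)$ and the CSC proportion
   $100 \cdot \mathrm{MTV_{csc}} / \mathrm{MTV}$, where $v$ is the voxel
   volume in cm³.

The key modelling assumption is *ordinal*, not distributional: clustering
requires only that the three populations differ in mean uptake, not that
they are Gaussian or of any particular proportion. When compartments are
not separated in SUV the three clusters still exist (the partition is always
well-defined) but their boundaries are a property of the histogram, not of
the biology; `end_to_end_recovery()` flags this regime rather than
pretending compartment recovery.

## Exact 1-D clustering

For one-dimensional data, an optimal $K$-means partition is always a set of
contiguous segments of the sorted values, so the global WCSS optimum can be
found by dynamic programming over segment boundaries — `petcsc` implements
this in C++ over the distinct values with multiplicity weights
($O(Kn^2)$ in the distinct-value count, trivially fast for lesion VOIs).
This is the default engine because it is deterministic (no seeding, no
restarts, invariant under voxel order) and serves as a built-in optimality
oracle for the generic Lloyd algorithm that clinical histogram software
typically uses. The Lloyd mode (k-means++ seeding under a caller seed,
relabelled so centroids ascend) is retained for fidelity comparisons; the
test suite and acceptance script verify on seeded mixture draws that the DP
partition's WCSS never exceeds the best of 50 Lloyd restarts.

Clustering operates on the full voxel-value list by default. A binned mode
(`bin_width`, e.g. 0.1 SUV) snaps values to bin centres with count weights,
mimicking pipelines that cluster histogram bins rather than voxels; on
typical lesions the difference is well below a voxel volume.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| fixed threshold | 2.5 | SUV | lesion definition, MTV/TLG; inclusive (≥) |
| avidity rule | SUVmax ≥ 2.5 | SUV | exclusion of non-avid tumors |
| relative fraction | 0.40 | — | MTV40%/TLG40% VOI |
| $K$ | 3 | — | histogram clusters |
| response cutoff | 1.75 | cm³ | predicted pCR iff MTVcsc < cutoff (strict) |
| cutoff round-up | 0.05 | cm³ | derivation step above the pCR maximum |
| survival horizon | 36 | months | DFS read-out |

Choices the measurement definition left open, and how they were fixed:

- **Connectivity** is the 26-neighbourhood, the usual choice for blob-like
  PET lesions; segmentation is seeded per lesion rather than enumerating
  whole-volume components, mirroring how a reader encompasses one tumor or
  node at a time. Contiguous breast and nodal uptake is therefore split by
  seed choice — a convention, not a measurement.
- **Threshold comparisons are inclusive** (a voxel at exactly SUV 2.5
  belongs to the lesion); the boundary behaviour matters only on synthetic
  data, where exact threshold values can occur.
- **The 40% VOI** is anchored at the hottest voxel of the fixed-threshold
  VOI and uses that VOI's SUVmax; ties for the hottest voxel break by lowest
  (z, y, x) index for determinism.
- **Patient-level MTVcsc** is the maximum across the patient's lesions
  (primary and nodal); in the source cohort the primary carried the maximum
  in most patients.
- **The cutoff is strict** (`<` 1.75): it derives from the highest pCR-group
  value, so the responder side must contain that maximum. The 1.75 figure is
  reconstructed from the observed maximum 1.7 cm³ by rounding up one 0.05
  step; the derivation rule is configurable because the original rounding
  convention was not recorded.

## Statistics

The cohort statistics are deliberately standard: cross-product odds ratios
with Woolf (log) 95% intervals; Pearson χ² without continuity correction;
Fisher's exact test by explicit enumeration of the margin-fixed table space
(feasible for the ≤ 5-column strata compared here, and cross-checked against
`stats::fisher.test`); logistic regression by IRLS (`stats::glm`,
deviance tolerance 1e−8, 100 iterations) with Wald intervals and p-values,
continuous covariates entered per unit (per cm³ for MTVcsc), per-analysis
complete-case deletion, and quasi-separation reported via a warning and
`converged = FALSE` rather than penalised away. Kaplan–Meier estimation and
the log-rank test wrap the `survival` package with Greenwood variance;
confidence intervals use the log(−log) transform by default so bounds
respect [0, 1] (the linear Greenwood interval is available), and an
event/censoring tie at the same time counts the event first. Months are
days/30.4375 when converting from dates.

## What the synthetic data emulates — and what it does not

The phantom generator lays three nested compartments (hot CSC core, mixed
shell, differentiated rim — the hot-core geometry of real lesions; a
random-blob mode exists) on a 4-mm grid in background of mean SUV 0.8
(typical breast background, safely below threshold; truncated normal, SD
0.2). Compartment SUVs are independent normals; ground truth (MTV, TLG,
MTVcsc, TLGcsc, SUVmax) is recomputed from the *realised* voxel values at
the 2.5 threshold, so a CSC voxel that happens to draw below threshold is
not counted as recoverable. Defaults (means 3 / 5.5 / 9, SD 0.2, counts
60 / 40 / 14) represent a well-separated, clearly avid lesion: 14 CSC
voxels = 0.896 cm³.

The cohort generator reproduces the published marginal structure: subtype
sizes 57 / 25 / 38 (HER2-positive / triple-negative / luminal), stratum pCR
rates 16/57, 6/25 and 0/38, log-normal patient-level MTVcsc per response
group with the median pinned to the printed medians (0.9 and 2.8 cm³) and
$\sigma$ set by reading the printed range as an approximate 95% range
(log-normality itself is motivated by the strong right skew of the residual
group: median 2.8, maximum 38), exponential relapse hazards
$-\log(0.90)/36$ and $-\log(0.72)/36$ per cutoff group, and uniform 3–90
month censoring spanning the study's follow-up.

What it does **not** emulate: scanner physics (point-spread blurring,
partial-volume effects, reconstruction noise correlations), lesion shape
irregularity, correlation between MTVcsc and the clinicopathologic
covariates (covariates are drawn from their marginals only), or
subtype-specific CSC biology beyond the rate parameters. Passing tests
therefore demonstrate that the *pipeline* measures what it defines —
segmentation, optimal clustering, parameter arithmetic, statistics — under
known ground truth; they cannot certify the biological claim that the top
cluster is CSC tissue, nor the clinical accuracy figures on real images.
Conversely the univariable odds ratios and subgroup accuracies *are* exact
recomputations, because they are closed-form functions of the published
contingency counts shipped with the package.

## Numerical and degeneracy choices

- VOIs with fewer than $K$ distinct SUVs are rejected as degenerate (with
  the count named) rather than padded.
- The DP cost recursion guards tiny negative round-off in prefix-sum SSQ;
  WCSS is accumulated in long double precision.
- Lloyd runs that produce coincident centroids are reseeded (up to 10
  attempts) because "most glycolytic cluster" is ill-defined under ties;
  the DP engine cannot tie on distinct values.
- Odds ratios with a zero cell require an explicit opt-in Haldane–Anscombe
  0.5 correction, and the result is flagged.
- A query beyond the last follow-up returns the last Kaplan–Meier step with
  a warning; an all-censored group stays at 100% with a degenerate CI.

## Problem sizes

The verification suite runs mixtures of 100–260 voxels (100 draws × 50
Lloyd restarts for the optimality check), one hundred 20³-voxel phantoms
for recovery, cohorts of 120 for the workflow and 21,000 for calibration
(pCR rates within ±1%, medians within ±0.1 cm³, 3-year DFS within ±4
percentage points), and n = 2000 for logistic coefficient recovery
(±0.15 on a true slope of −2 per cm³). These sizes give the checks sharp
tolerances while keeping a full run in seconds.

## Limitations

The package measures a *definition* of CSC metabolism. Direct biological
validation (stemness markers, expression signatures) is outside its scope;
the luminal subtype illustrates why caution is needed — low MTVcsc there
does not predict response, plausibly because quiescent CSCs are hypo- not
hyper-metabolic. DICOM SUV pipelines (decay correction, lean-body-mass
variants), PSF/partial-volume correction, Cox modelling and competing risks
are deliberately out of scope.
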