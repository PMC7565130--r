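# petcsc

Quantifying cancer-stem-cell (CSC) metabolism in breast tumors from a single
pretreatment ¹⁸F-FDG PET scan.

Proliferative CSCs are markedly more glycolytic than the differentiated
cancer cells that make up the bulk of a tumor, so the hottest voxels of an
FDG-avid lesion should over-represent the CSC compartment. `petcsc`
implements a voxel-histogram pipeline that turns that observation into
imaging biomarkers, and the downstream statistics used to evaluate them as
predictors of response to neoadjuvant chemotherapy (NAC) and of disease-free
survival (DFS):

1. **Segmentation.** A lesion VOI is the 26-connected component of voxels
   with SUV ≥ 2.5 around a seed; tumors with SUVmax < 2.5 are excluded as
   non-avid. A companion VOI at 40% of SUVmax gives MTV40%/TLG40%.
2. **Histogram clustering.** The VOI's voxel SUVs are partitioned into
   K = 3 clusters minimising the within-cluster sum of squares. The default
   engine solves the 1-D problem *exactly* by dynamic programming on the
   sorted values (an optimal 1-D k-means partition is contiguous in sorted
   order); Lloyd k-means with k-means++ seeding is available as a fidelity
   mode.
3. **Parameters.** With voxel volume *v* (cm³; 0.064 for the 4 × 4 × 4 mm
   grid), the most glycolytic cluster *C*₂ yields

   - MTVcsc = |*C*₂| · *v*  TLGcsc = Σ_{x∈C₂} SUV(x) · *v*
   - CSC proportion = 100 · MTVcsc / MTV,

   alongside conventional SUVmax, MTV = |VOI| · *v* and
   TLG = mean SUV · MTV. Patient-level MTVcsc is the maximum over lesions.
4. **Response prediction.** MTVcsc < 1.75 cm³ (the highest pCR-group value,
   rounded up to the next 0.05) predicts pathologic complete response;
   confusion tables and accuracies are tabulated by subgroup.
5. **Cohort statistics and survival.** 2×2 odds ratios with Woolf
   intervals, Pearson χ², enumeration-exact Fisher tests, logistic
   regression (per-cm³ OR for MTVcsc), Kaplan–Meier DFS with Greenwood /
   log(−log) intervals, and the two-group log-rank test.

Because no patient images are distributable, the package ships a synthetic
module: digital phantoms with a differentiated rim, mixed shell and hot CSC
core whose ground truth is recorded from the realised voxels, and synthetic
120-patient cohorts calibrated to the published subtype sizes, pCR rates,
MTVcsc distributions and relapse hazards.

## Worked example

```r
library(petcsc)

# a phantom with a 14-voxel CSC core at SUV 9 over shells at 5.5 and 3
spec <- phantom_spec(means = c(3, 5.5, 9), sds = c(0.2, 0.2, 0.2),
                     counts = c(60, 40, 14), seed = 20260928)
ph  <- generate_phantom(spec)
voi <- segment_fixed_threshold(ph$volume, ph$truth$seed_voxel)  # SUV >= 2.5
part <- cluster_suv_histogram(voi)            # exact DP, K = 3
csc_parameters(voi, part)
#>   mtv_csc  tlg_csc csc_proportion
#> 1   0.896 8.066984       12.38938
ph$truth$mtv_csc
#> [1] 0.896
```

The 14 CSC voxels are recovered exactly (14 × 0.064 cm³ = 0.896), and
MTVcsc = 0.896 < 1.75 classifies the case as a predicted responder
(`classify(0.896)` is `TRUE`). On the statistics side, the published
univariable T-stage cells give

```r
odds_ratio(20, 33, 2, 27)
#> $or
#> [1] 8.181818
#> $ci
#> [1]  1.754042 38.164502
```

i.e. OR 8.18 (95% CI 1.75–38.16) for lower T stage and pCR.

The full analysis is organised as numbered drivers under `analysis/`
(simulate → lesion parameters → response/statistics → survival), each
printing what it found and writing its tables under `results/`.

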