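# longsem

Longitudinal measurement invariance, second-order latent growth curve
models, and voxel-wise structural equation mapping — in one package, on
one estimation engine.

## The problem

Developmental studies often ask two questions at once: *does a multi-item
scale measure the same construct at every assessment wave*, and *what
predicts how individuals change*? Answering the first requires testing
longitudinal measurement invariance (configural → weak → strong, with a
partial-invariance fallback); answering the second requires a growth
model on the latent trait rather than on error-prone sum scores; and in
imaging cohorts the predictor of interest may be *every voxel of a
baseline brain volume* in turn. `longsem` implements this chain for
psychologists and imaging researchers:

* a mean-and-covariance-structure SEM engine with **full-information
  maximum likelihood** (casewise over each participant's observed
  subvector, so monotone and intermittent dropout need no imputation),
  analytic gradients, effects-coding identification, sandwich standard
  errors and a Satorra–Bentler-style scaling factor;
* **fit statistics**: likelihood-ratio T, RMSEA
  `sqrt(max(0, (T − df)/(df (N−1))))` with noncentral-χ² 90% intervals,
  CFI against the independence baseline, scaled difference tests, and
  score-test **modification indices**;
* the **invariance ladder** with the acceptance rule ΔCFI ≤ 0.01 and
  new-RMSEA-within-previous-CI, plus a greedy partial-invariance search
  that frees drifted intercepts by modification index;
* a **second-order LGCM** (intercept/slope on the occasion factors,
  default slope basis 0, 0.5, 1; latent basis optional) with
  time-invariant covariates and StdYX/StdY standardization;
* a **voxel-wise stage**: each in-mask voxel predicts the latent slope
  (or intercept), maps are thresholded at p < 0.001 (uncorrected, stated
  loudly) with cluster extent > 50 voxels under 6/18/26-connectivity,
  NIfTI in and out;
* a **synthetic-data generator** that emulates a large three-wave
  adolescent personality panel (1808/1414/1282 participants, planted
  intercept drifts, negative intercept–slope correlation, covariate
  effects, smoothed volumes with a slope-coupled spherical region) with a
  complete ground-truth record.

## Worked example

Simulate the default study conditions and run the whole chain:

```r
library(longsem)

cfg   <- simConfig(seed = 42)   # defaults: N = 1808/1414/1282, 5 drifted items
panel <- genItemPanel(cfg)
rep   <- runLadder(panel)
rep
#> Measurement-invariance ladder
#>   configural T =   547.87  df =  555  RMSEA = 0.000 (0.000-0.007)  CFI = 1.000
#>   weak       T =   570.73  df =  577  RMSEA = 0.000 (0.000-0.007)  CFI = 1.000
#>   strong     T =   850.54  df =  599  RMSEA = 0.015 (0.013-0.018)  CFI = 0.984
#>   partial    T =   619.33  df =  591  RMSEA = 0.005 (0.000-0.009)  CFI = 0.998
#>   freed intercepts (in order): 4, 7, 8, 12
#>   final level: partial
```

Loadings equal across waves are accepted (weak); equal intercepts are
rejected — the drop in CFI and the jump of RMSEA out of the weak model's
interval flag drifting items — and the partial search frees four of the
five planted drifted intercepts before the rules pass again. The growth
model then sits on the accepted partial-invariance measurement model:

```r
spec <- buildLGCM(rep$finalSpec, growthSpec(),
                  covariates = c("sex", "depression"), panel = panel)
est  <- estimateGrowth(spec, panel)
est
#> Second-order growth model estimates
#>                   parameter estimate     se
#>              intercept mean   2.8056 0.0311
#>          intercept variance   0.6290 0.0338
#>                  slope mean  -0.2233 0.0286
#>              slope variance   0.0773 0.0557
#>  intercept-slope covariance  -0.0352 0.0329
#> intercept-slope correlation: -0.159
#> covariate paths (raw / stdyx / stdy):
#>  outcome  predictor              label     raw   stdyx    stdy
#>    icept        sex        b_sex_icept  0.4961  0.2887  0.5782
#>    slope        sex        b_sex_slope  0.1383  0.2406  0.4819
#>    icept depression b_depression_icept  0.2112  0.2432  0.2462
#>    slope depression b_depression_slope -0.0194 -0.0668 -0.0676
```

The trait declines on average (negative slope mean), individuals differ
in level and change, the level–change correlation is negative, and the
female intercept advantage planted by the generator is recovered
(`stdy = 0.58` against a generating value equivalent to 0.60). Fit:

```r
fitStatistics(est$fit)
#> T = 700.061, df = 660, c = 1.000, N = 1808
#> RMSEA = 0.006 (90% CI: 0.000-0.009), CFI = 0.997
```

The voxel-wise stage takes a 4D volume stack aligned with the panel:

```r
vols <- genVolumes(cfg, panel@meta$truth$slope)
base <- buildLGCM(rep$finalSpec, growthSpec(), panel = panel)
map  <- mapVoxelPredictor(panel, vols$volumes, vols$mask, base,
                          target = "slope", affine = vols$affine)
thresholdCluster(map, pThresh = 0.001, minExtent = 50)
```

which returns the surviving clusters with sizes and peak world-mm
coordinates (empty table if nothing survives — not an error).

A thin command line wraps the same functions
(`inst/cli/longsem simulate|invariance|growth|voxelmap|report`), with
YAML configs, flag overrides, and the resolved configuration embedded in
every artifact.

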