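---
title: "Modelling longitudinal trait change and its voxel-wise brain predictors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling longitudinal trait change and its voxel-wise brain predictors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longsem)
```

# The analysis chain

`longsem` implements a three-stage inference chain for multi-item scales
administered repeatedly to the same participants, with an optional
neuroimaging stage:

1. **Longitudinal measurement invariance.** Before change in a latent trait
   can be interpreted, the scale's psychometric parameters must be shown to
   be stable over occasions. The package fits the standard ladder —
   configural (same one-factor structure per occasion), weak (equal
   loadings), strong (equal intercepts) — and, when strong invariance
   fails, searches for a partial-invariance model that frees the smallest
   set of intercepts.
2. **Second-order latent growth curve model (LGCM).** Growth factors
   (intercept, slope) are placed on the occasion-specific trait factors of
   the accepted measurement model, with time-invariant covariates
   regressed onto both growth factors.
3. **Voxel-wise mapping.** For every in-mask voxel of a stack of baseline
   3D volumes, the voxel value enters the LGCM as one more predictor of
   the latent slope (or intercept); the resulting 3D statistic maps are
   thresholded voxel-wise and by cluster extent.

All stages share one estimation engine: a mean-and-covariance-structure
SEM with full-information maximum likelihood (FIML) over each
participant's observed subvector, so monotone and intermittent dropout are
handled without imputation or listwise deletion (covariates are the one
exception: rows with missing covariates are dropped with a recorded
count, since covariates enter as exogenous conditioning variables).

# The model and its estimation

## Parameterization

Models are expressed in an all-y LISREL form: observed variables
$y = \tau + \Lambda \eta + \varepsilon$ with
$\eta = \alpha + B\eta + \zeta$, giving implied moments

$$\Sigma(\theta) = \Lambda (I-B)^{-1} \Psi (I-B)^{-\top} \Lambda^\top + \Theta,
\qquad \mu(\theta) = \tau + \Lambda (I-B)^{-1} \alpha.$$

Every matrix cell is an affine function of the free-parameter vector.
Equality constraints are shared labels; the *effects-coding*
identification is encoded as linearly dependent cells: per factor and
occasion the loadings sum to the number of indicators and the intercepts
sum to zero, which leaves latent means and variances free at every
occasion and puts them on the scale of the items. For the intercepts the
constraint is imposed per occasion while intercepts are occasion-specific
(configural, weak); once intercepts are at least partially equal across
occasions a single occasion-1 constraint identifies the remaining latent
means through the invariant items. This makes the degrees-of-freedom
ladder exact: equating one loading or intercept over three occasions
contributes 2 df, so a 12-item scale yields $\Delta df = 22$ for each of
the configural$\to$weak and weak$\to$strong steps, and freeing $k$
intercepts in the partial model returns $2k$ df.

## FIML, saturated and baseline models

Participants are grouped by missingness pattern; each pattern contributes
through its sufficient statistics $(n_k, \sum x, \sum xx^\top)$, which
makes one likelihood evaluation independent of $N$. The objective and its
analytic gradient (chain rule through the affine cell maps) feed a
quasi-Newton optimizer (`nlminb`). Variances are deliberately left
unconstrained so Heywood cases remain representable; negative variance
estimates are flagged, never truncated. Failed first attempts trigger up
to three jittered restarts under a recorded seed.

The test statistic is the likelihood-ratio form
$T = 2(\ell_{sat} - \ell_{model})$. With incomplete responses the
saturated log-likelihood is obtained by an EM algorithm over unstructured
$(\mu, \Sigma)$ (closed form when complete). The CFI baseline is the
independence model with free means and variances, whose FIML solution
factorizes per variable and is available in closed form.

## Fit indices and decisions

RMSEA uses the $N-1$ denominator,
$\sqrt{\max(0, (T - df)/(df\,(N-1)))}$, which reproduces conventional
printed values; its 90% interval inverts the noncentral-$\chi^2$ tail
probabilities in the noncentrality parameter. CFI is
$1 - \max(T-df,0)/\max(T_b-df_b, T-df, 0)$. A ladder level is accepted
when the CFI decrease is at most 0.01 **and** the new RMSEA lies inside
the previous level's 90% CI; the Satorra–Bentler scaled difference test is
computed and reported at every step but is deliberately not decisive —
with large samples trivial loading differences reach significance, so
practice accepts a level whose approximate fit indices are unchanged.

A robust ("MLR-style") layer is available on request: sandwich standard
errors from casewise scores, and a scaling factor
$c = \mathrm{tr}(U\Gamma)/df$ with $U$ the normal-theory projection
complement at the model-implied moments and $\Gamma$ the
moment-score-based asymptotic covariance. On the multivariate-normal data
the generator produces, $c \approx 1$ and the scaled difference reduces to
the plain one; the machinery exists so that the same decisions can be
reported in the robust form.

## Modification indices and the partial search

When strong invariance is rejected, candidates free one item's
intercepts across occasions (adding 2 df each). Each candidate's
modification index is a score test at the constrained solution: the
gradient of the relaxed model at the embedded estimate, combined with the
expected (normal-theory) information in moment space — assembled
analytically per missingness pattern and verified in the tests against
central differences of the analytic moment gradient. The search is greedy:
free the largest index, refit, stop when the acceptance rules pass against
the weak level, never freeing the last invariant intercept. A
standardized-residual-moment report accompanies the indices for human
inspection but does not drive the automation. Score tests track actual
refit drops closely in the moderate range and overshoot for very large
violations; since only the *ranking* drives the search, this does not
affect which items are freed.

## Growth structure

The second-order LGCM fixes first-order latent intercepts to 0 (their
means are absorbed by the growth factors under effects coding), loads the
intercept factor with 1 at every occasion, and uses the slope basis
$(0, 0.5, 1)$ by default — occasions roughly at ages 14, 16.5 and 19
mapped onto a unit span, consistent with the near-linear freed middle
loading reported for such cohorts; $(0, 1, 2)$ or a latent basis
(endpoints fixed, interior free — costing exactly one df) are available.
Occasion disturbances are free and uncorrelated, so the latent covariance
of three occasions is saturated and the linear-basis restriction is purely
on the mean structure. Covariates regress onto both growth factors
regardless of significance; their own moments are fixed at sample values
(exogenous conditioning), and degrees of freedom count sample moments
minus free parameters with the exogenous block excluded symmetrically.
Standardization uses model-implied variances: `stdyx` multiplies by
SD(predictor)/SD(outcome), `stdy` (binary dummies) divides by SD(outcome)
only.

## Voxel-wise stage

Each voxel's values are standardized across participants and inserted as
an exogenous predictor of the target growth factor. The default
`fixed_measurement` mode freezes loadings, intercepts and residual
structure at the base (no-voxel) solution and refits only the structural
block per voxel, warm-started from the base fit; `full_refit` frees
everything. The two agree on coefficient sign and closely on z for
well-separated effects (tested), at two orders of magnitude different
cost. Two-sided p values use a Student-t reference with $N - q$ degrees
of freedom ($q$ free parameters): a finite-sample Wald calibration chosen
because the normal reference visibly inflates the far tail at the sample
sizes the synthetic studies use; the normal reference remains available.
Per-voxel power is bounded by the slope factor's measurement
reliability — at a few hundred participants even a voxel that nearly
determines the slope caps out near $|z| \approx 3$–4 — which is why the
planted-effect demonstrations use larger samples than the null
calibration runs.

Thresholding follows the conservative uncorrected convention: binarize
$p < 0.001$ within the mask, label connected components (default
18-connectivity; 6 and 26 available and recorded), and keep components
strictly larger than 50 voxels. No multiple-comparison correction is
applied, and the output metadata says so loudly. Peaks are reported in
world mm through the (1-based) voxel-to-world affine.

# The synthetic-data generator

`simConfig()`/`genItemPanel()`/`genVolumes()` generate data with the
statistical structure the analysis assumes, with a full ground-truth
record. The defaults emulate a large three-occasion adolescent personality
panel:

* **Sample and dropout.** 1808 participants at baseline, 1414 and 1282
  observed at the later occasions, split into completers, dropout after
  baseline, dropout after occasion 2, and intermittent return (100 by
  default; the three published occasion counts do not pin this split
  down, so a plausible value was fixed once). Dropout is assigned
  completely at random within the pattern sizes, matching the reported
  absence of selective dropout.
* **Measurement.** One factor, 12 items; raw loadings are the reference
  occasion-1 standardized loading profile rescaled to mean 1 (effects
  coding); item intercept deviations sum to zero; residual SDs are chosen
  so each item's occasion-1 standardized loading equals its configured
  target (a consequence is that all items share total SD
  $\approx 1.58$). Five items (2, 4, 7, 8, 12) carry intercept drifts of
  0.3 response units at occasions 2–3 with alternating sign by default;
  drift 0 gives exactly invariant data.
* **Growth.** Intercept mean 2.8, SD 0.8; slope mean $-0.21$, SD 0.30;
  intercept–slope correlation $-0.2$; disturbance SD 0.25. The means and
  SDs were fixed so the *standardized* growth parameters match the
  reference values (3.5, $-0.7$, $-0.2$) on a plausible 1–5 response
  scale.
* **Covariates.** Sex (female dummy, $p = 0.511$) with raw effects 0.48
  (intercept) and 0.096 (slope); depression and puberty as standard
  normal scores with small effects; nine sites with zero offsets by
  default; age as a z-score with zero effect. Values were back-computed
  from the reference standardized coefficients where available.
* **Volumes.** A 20×20×20 grid of 2 mm voxels ("desk scale"), smooth
  background (Gaussian kernel, FWHM 8 mm, half-sample-reflective and
  sum-preserving), spherical mask (radius 8.5 voxels, ~2500 voxels), and
  an effect sphere of radius 4 voxels (~257 voxels, comfortably above the
  50-voxel extent threshold) whose values gain
  `coupling * slope + noise`.
* Likert discretization is off by default so the continuous-data
  estimators are exactly correctly specified; switching it on gives the
  coarsened 1–5 responses of real questionnaires.

What passing tests on these data do **not** show: robustness to ordinal
coarseness (items are generated continuous by default), to non-normal
latent distributions, to informative dropout, to real VBM preprocessing
(segmentation, registration, modulation are out of scope — volumes are
synthetic fields, not anatomy), or to spatially structured noise beyond
stationary smoothing.

# Numerical choices and degenerate inputs

* Non-positive-definite implied pattern covariances act as optimizer
  barriers (large objective, zero gradient), not errors.
* Singular observed information yields `NA` standard errors plus a flag,
  never zeros.
* A scaled-difference correction $cd \le 0$ is an error by design; a
  negative scaled difference statistic is reported with a warning flag.
* `T = df` collapses the lower RMSEA CI bound to zero; `df = 0` makes
  RMSEA an error (undefined), and a saturated fit reports `T = 0`.
* The partial search never frees the last invariant intercept; if the
  rules cannot be satisfied above that floor, the result says "no
  acceptable partial model" rather than returning a degenerate fit.
* Warm starts across the ladder (and per voxel) transfer estimates
  between specifications by matching parameter cells through variable
  names, so differently sized models interoperate.

# Problem sizes used in the shipped studies

The replicate studies that accompany the package (test suite) use
N = 1000 panels with the scaled dropout profile for parameter recovery
(200 replicates) and invariance behaviour (100 null and 100 planted
replicates at 0.5-item-SD drift), N = 200 pure-noise volumes on the 20³
grid for null voxel calibration, and N = 500 with coupling 0.8 for the
planted-effect localization — the latter larger for the reliability-bound
power reason above. These sizes are the package's own choice of a
desk-scale design whose Monte-Carlo error is small enough for the stated
checks.

# Known limitations

* Likert items are treated as continuous throughout; no categorical
  estimator is provided.
* The robust layer implements the sandwich/scaling machinery only; no
  mean-and-variance-adjusted statistics.
* Single-group analyses only (the invariance tested is longitudinal, not
  multi-group), linear or latent-basis growth only, and single-score
  covariates.
* The voxel stage is massively univariate by design; it inherits every
  caveat of uncorrected VBM-style inference, which the output restates.

# A compact end-to-end run

```{r endtoend, eval = FALSE}
cfg <- simConfig(n = 600, occasionCounts = c(600L, 469L, 425L),
                 intermittentReturn = 33L, seed = 42)
panel <- genItemPanel(cfg)

ladder <- runLadder(panel)                  # configural / weak / strong (+ partial)
spec <- buildLGCM(ladder$finalSpec, growthSpec(),
                  covariates = c("sex", "depression"), panel = panel)
growth <- estimateGrowth(spec, panel)

vols <- genVolumes(cfg, panel@meta$truth$slope)
base <- buildLGCM(ladder$finalSpec, growthSpec(), panel = panel)
map <- mapVoxelPredictor(panel, vols$volumes, vols$mask, base,
                         target = "slope", affine = vols$affine)
thresholdCluster(map, pThresh = 0.001, minExtent = 50)
```
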