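---
title: "Correcting regression-dilution bias in brain-age prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting regression-dilution bias in brain-age prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agebias)
```

## The problem

A brain-age model predicts chronological age Ω from imaging features and
reports the per-subject delta Δ = predicted − Ω. When the features carry
measurement noise, the fitted regression slope is attenuated toward zero
(regression dilution): predictions are pulled toward the training-set
mean age, so Δ trends negatively with age. A population-level view makes
the geometry exact. If predictions behave as

$$\widehat{y} = p + a\,(\Omega - p) + \varepsilon,
\qquad \varepsilon \sim N(0, \sigma^2),$$

with attenuation factor $a \in [0, 1]$ and pivot age $p$, then

$$\Delta = (a - 1)\,\Omega + (1 - a)\,p + \varepsilon,$$

a line with slope $a - 1$ and intercept $(1 - a)p$. Uncorrected deltas
are therefore confounded with age, and anything correlated with age
(including diagnosis) is confounded with them.

## The correction schemes

**Offset correction** (`fit_offset_model(scheme = "proposed")` +
`apply_proposed()`). Regress the training deltas on age by OLS,
Δ = αΩ + β, and subtract the fitted per-subject offset αΩ + β from each
raw prediction. Two exact consequences, both enforced by tests:

* On the fitting set the adjusted delta is an OLS residual, so its
  Pearson correlation with age is 0 to machine precision.
* `Var(Δ_adj) ≤ Var(Δ)` on the fitting set — the correction can only
  remove age-explained variance.

**Cole-style rescaling** (`scheme = "cole"` + `apply_cole()`). Regress
the raw predictions on age, predicted = αΩ + β, and rescale each
prediction as (predicted − β)/α. The adjusted delta equals the offset
scheme's residual divided by α, so it is equally orthogonal to age, but
its variance is inflated by 1/α² — badly when attenuation is strong
(small α). Because rescaling is affine with positive slope, the squared
Pearson correlation between predicted and chronological age is unchanged
by it; this is why R² is defined here as the squared correlation rather
than 1 − SSE/SST, and why the two definitions must not be mixed when
comparing arms. Slopes with |α| below `slope_floor` (default 0.05) are
refused: dividing by a near-zero slope would blow up the predictions
without bound.

**Covariate adjustment** (`le_group_test()`). Fit Δ ~ age + group and
test the group effect by a nested-model F test, reporting
covariate-adjusted group means (via `emmeans`) at the overall mean age.
This needs no per-subject correction but also produces none: it is a
group-level procedure only.

The offset and rescaling models are always fitted on the **out-of-fold
cross-validation predictions** of the training set, never on in-sample
predictions of the final refit model (which would understate the bias
optimistically) and never on test data (which would leak the test ages'
bias into the correction). The fit records its provenance.

## The estimation harness

`fit_regressor()` regresses age on the `feat_*` columns with one of two
backends:

* `"svr"` — linear epsilon-insensitive support vector regression with
  the common library defaults (cost 1, epsilon 0.1). Features are
  standardized by the training mean/SD (SVR is scale-sensitive); the
  standardization is stored in the model and re-applied at prediction
  time.
* `"ols"` — ordinary least squares on the same standardized features.
  Every bias-adjustment property in this package is backend-agnostic;
  the OLS backend exists so tests of the correction schemes do not
  depend on SVR numerics, and because attenuation has a closed form
  under OLS.

`cross_val_predict()` partitions subjects into k seeded folds whose
sizes differ by at most one, with no stratification by age (none is
assumed by the correction theory, and the folds are large at the
intended n). Missing feature values are rejected rather than imputed.

## What the synthetic cohort generator emulates

`generator_config()`/`generate_cohort()` draw, per subject: age uniform
on [47, 94] years, a latent brain age equal to age plus a group-specific
acceleration, and feature values linear in latent brain age with
additive Gaussian noise. Defaults mimic a regional FDG-PET SUVR panel —
12 regions, baseline 1.25, slope −0.003 SUVR per year, noise SD 0.05
SUVR — and cohort sizes 750 CN / 561 MCI / 362 AD. The uniform age
distribution is a modeling choice (only the age span is given for the
cohorts this emulates); it has a closed-form variance (47²/12 ≈ 184 y²),
which makes every attenuation calculation below checkable by hand.

The generator reproduces the statistical structure the correction
schemes care about — an age signal, noise-induced attenuation, additive
clinical acceleration — and nothing else. It does not emulate realistic
inter-regional covariance, nonlinear aging trajectories, scanner or site
effects, or sex differences. Tests passing on it show that the
machinery is correct under the stated generative model, not that any
particular clinical dataset satisfies that model.

`simulate_predictions()` additionally bypasses the regressor entirely:
raw predictions are generated directly from the attenuation equation
above, so the bias is analytically known. Its calibration preset
(attenuation 0.3, pivot 71.43 y, noise SD 5.13 y) was frozen after
deriving its implications analytically and confirming them with a
10⁶-sample simulation: for ages uniform on [47, 94] the delta-on-age
line has slope −0.7 and intercept 0.7 × 71.43 = 50.0, and the delta–age
correlation is

$$r = \frac{(a-1)\,\mathrm{sd}(\Omega)}
{\sqrt{(1-a)^2\,\mathrm{Var}(\Omega) + \sigma^2}} = -0.880.$$

These are the magnitudes typical of a strongly attenuated FDG-PET
brain-age model, which is the regime where the choice of correction
scheme matters most.

## Calibrating clinical group effects

The generator's group offsets are **latent** accelerations: they enter
the features (or the simulator) before attenuation, so a latent offset
of δ years surfaces in offset-adjusted deltas as only a·δ years, while
Cole rescaling (dividing by the fitted slope ≈ a) restores ≈ δ. The
package's defaults encode a clinical regime in which offset-adjusted
deltas separate CN/MCI/AD by about 2.0 and 4.1 years with a within-group
spread of about 3.44 years (effect sizes d ≈ 0.58 and 1.19 against
controls). Under attenuation 0.3 that corresponds to latent
accelerations of 2.0/0.3 ≈ 6.7 and 4.1/0.3 ≈ 13.7 years — which is
exactly where Cole-rescaled deltas land, and the group-contrast tests
use this parameterization so that both schemes' group means have known
truth. The `generate_cohort()` defaults keep the more conservative
{MCI +2.0, AD +4.1} latent offsets for generic use; any study-specific
regime is one `group_offsets` argument away.

## Numerical and statistical choices

* **R²** is the squared Pearson correlation between chronological and
  predicted age (affine-invariant; see above).
* **Levene's test** centers at the group mean (the classic form); the
  median-centered Brown–Forsythe variant is available via
  `center = "median"`. Both delegate to `car::leveneTest`.
* **Bootstrap MAE comparison** resamples subjects (paired across the two
  arms) with replacement; the two-sided p-value is
  `2·min(P(diff ≤ 0), P(diff ≥ 0))` with a `+1/(n_boot+1)` continuity
  guard so p is never exactly zero. CI-overlap rules are not a defined
  test for paired errors, so the sign construction is pinned instead.
  All bootstrap CIs are percentile (not BCa), with n_boot = 1000 by
  default; every randomized report records its seed.
* **Tie-breaks and degeneracies**: constant-age training sets, single
  subjects, groups of one, zero pooled SD and near-zero Cole slopes all
  raise typed errors rather than propagating NaN. A Cole fit whose slope
  is numerically zero (|α| < 1e-12 — OLS never returns an exact zero)
  is flagged unusable at fit time.
* **Seeding**: every stochastic operation takes an explicit seed, and
  `run_experiment()` derives stage seeds from one master seed by fixed
  offsets (generator +1001, split +2002, folds +3003, bootstraps +4004),
  so a stage can be reproduced in isolation and two runs with one seed
  are identical end to end.
* **Serialization**: offset models are JSON with 17 significant digits
  (exact IEEE round trip); cohort and prediction tables are plain CSV
  with '.' decimals.

## Problem sizes in the test suite

The test and validation suites run at the design's native scale where it
is cheap (n = 675 training subjects, 75/561/362 test groups — the ANOVA
df of (2, 995) is asserted exactly) and use 100–1000 replicates for the
stochastic recoveries: 200 replicates for the calibration-preset
geometry (slope −0.7 ± 0.01, intercept 50 ± 0.8, r −0.88 ± 0.01), 100
for group-separation power, and 1000 replicate pairs for the type-I
calibration of the bootstrap MAE comparison and Levene test (5% ± 2% at
α = 0.05).

## Limitations

* The offset is linear in age. Modalities with nonlinear delta–age
  relationships would need a nonlinear basis, which this package does
  not provide.
* The generator's linear-Gaussian feature model cannot probe robustness
  to heteroscedastic noise, heavy tails, or age-dependent feature
  covariance.
* `le_group_test()` pins the common ANCOVA form (no age×group
  interaction, type-I nested F on the group term after age); it yields
  group-level inference only.
* Accuracy metrics on real cohorts depend on everything upstream of this
  package (image processing, feature extraction, cohort composition);
  the synthetic results here validate the correction machinery, not any
  specific imaging pipeline.
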