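---
title: "Normative deviation components: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative deviation components: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
models it fits, the parameters that matter, what the synthetic-cohort
generator does and does not emulate, and the places where the design was
genuinely open and a choice had to be made.

## 1. The analysis in one paragraph

Regional morphometry (cortical thickness over 68 parcels, subcortical
volume over 14 structures) from a healthy multi-site reference cohort is
harmonized across sites, then modelled per region and sex as a
fractional-polynomial function of age plus a global-size covariate.
Patients are scored as deviations `z = (observed - predicted) / RMSE`.
The patients-by-regions deviation matrix is made nonnegative and
factorized by orthonormal projective NMF into spatial components `W` and
subject loadings `H`; the rank is chosen from split-half stability and
the reconstruction-error gradient. Loadings are related to behavior by
partial least squares with permutation and bootstrap inference, and
component maps are related to molecular predictor maps by multilinear
regression with dominance analysis, variogram-matched spatial null
models, and distance-dependent cross-validation.

## 2. Site harmonization

`harmonize()` implements parametric empirical-Bayes location/scale
adjustment. Each region is regressed on site indicators plus a
*preserved design*; the standardized residuals' per-site means and
variances are shrunk across regions (normal prior on locations,
inverse-gamma on scales, iterated to convergence) and removed.

The preserved design is an age basis (powers 0.5 and 2 of age/10) plus
sex — deliberately *not* the global-size covariates (mean CT, TIV).
Those are measured quantities that carry the site effect themselves;
conditioning on them would launder part of the site effect back into
the data. They belong to the normative models downstream, where the
reference is already harmonized. With a single site the function is the
identity, so harmonization never manufactures adjustments where no site
contrast exists.

Transfer: the patient/control site receives *no* new harmonization
parameters — the fitted normative model is applied directly. This
mirrors the transfer argument of covariate-preserving harmonization
(no recalibration when moving to a new site), and it is testable here:
on synthetic controls from an unseen site the extreme-deviation rate
(`|z| > 1.96`) sits at its nominal 5%.

## 3. Normative growth models

For each (region, sex) cell, `fit_normative()` searches all FP1 (8
powers) and FP2 (36 pairs, repeats meaning `x^p` and `x^p log x`; power
0 meaning `log x`) age bases over the grid {-2, -1, -0.5, 0, 0.5, 1, 2,
3}, each with an intercept and the class covariate (mean CT for
thickness, TIV for volume), and keeps the minimum-BIC model fitted by
OLS. Ages are divided by 10 before exponentiation; this conditions the
design matrix and rescales coefficients without changing predictions.

Choices worth knowing:

* **BIC, not AIC** (configurable): the reference cohort is large and we
  prefer consistency — the linear model should win when the truth is
  linear. The BIC-selected model never has a higher BIC than the
  linear-age model, by construction of the search.
* **RMSE** is the df-adjusted residual root-mean-squared error of the
  selected model on the *full* reference fit (not cross-validated), so
  that reference deviations have mean 0 and SD ~ 1 by construction and
  fresh controls score ~ N(0, 1).
* **Power-pair identifiability.** Fractional-polynomial bases are
  nearly collinear over the pediatric age range 3-18: pairs such as
  (0.5, 2), (1, 2) and (0, 2) produce fitted curves that differ by well
  under 1% of the curve's range at realistic noise. The *curve* is
  identified; the power *labels* are not. Tests therefore assert curve
  recovery (and that the generative pair is the modal selection), and
  any consumer of the stored powers should treat them as a basis
  choice, not a biological finding. A global-size covariate that is
  itself age-structured (mean CT is) absorbs part of the age curve and
  widens this ambiguity further.

`deviation_scores()` applies the stored (powers, coefficients, RMSE)
per region and sex; subjects outside the training age range are flagged
as extrapolated rather than refused.

## 4. Nonnegativity and opNMF

Deviations are signed; opNMF needs a nonnegative input
(`to_nonnegative()`):

* `shift` (default): subtract the global minimum. Preserves every
  between-subject and between-region contrast and the additive
  parts-based geometry; a single offset is recorded for inversion.
* `abs`: magnitudes only — appropriate when the sign of deviation is
  irrelevant.
* `split`: stack positive and negative parts (82 -> 164 rows), keeping
  sign information at the cost of doubling the region dimension.

The default is `shift` because the planted pathology in the generator
(and the plausible pathology in pediatric epilepsy) is directional
thinning; `abs` and `split` exist because signed deviations can carry
both increases and decreases.

`opnmf_fit()` minimizes `||X - W W'X||_F` by the one-term multiplicative
update `W <- W * (AW) / (W(W'AW))` with `A = XX'` precomputed,
`eps = 1e-16` guarding denominators, per-iteration L2 column
normalization, and convergence on the relative Frobenius change of `W`
(default `tol = 1e-5`, `max_iter = 50000`). Initialization is sparse
NNDSVD (zeros stay zero, but a tiny floor of 1e-12 lets multiplicative
updates re-activate entries). Given `(X, W0)` the fit is bit-for-bit
deterministic.

Two honest caveats about this update, visible in the tests: it has no
descent *guarantee* (small transient increases of the objective occur),
and independently initialized fits at different ranks can land in
different basins, so the reconstruction error is only monotone in `k`
at the resolution of those basins. Both behaviors are inherited from
the projective-NMF update itself; the tests assert the substantive
properties (large overall descent, near-optimal subspace error, error
decreasing from low to high rank).

## 5. Rank selection

`stability_analysis()` repeats, for each rank: split subjects in half
at random (the larger half absorbs an odd subject), fit both halves,
pair the component columns of the two `W` matrices by Hungarian
assignment on their cosine-similarity matrix, and record the mean
Pearson correlation of paired columns; the reconstruction-error
gradient `error(k) - error(k-2)` is computed on the same split fits for
variance reduction. Defaults follow the study design: ranks 2-20, 100
splits. Half-cohort fits default to a 5,000-iteration cap and
`tol = 1e-4` — only the relative structure across ranks matters there,
and the cap keeps 100-split runs affordable.

`select_k()` returns the largest rank before the first sustained
stability decline (two consecutive drops > 0.01) plus a
gradient-plateau indicator; the selection is advisory and the full
curve is always returned, because in practice this choice is made by
inspecting the curve.

## 6. Behavioral PLS

`bpls_fit()` listwise-deletes incomplete rows (complete-case analysis,
with per-subset sample sizes reported by `pls_subsets()`), z-scores
both blocks, and decomposes the cross-correlation matrix. Inference:

* **Permutation** (default 10,000): brain rows shuffled, singular values
  compared position-wise, add-one p-values. Calibration is verified by
  simulation (type-I error within [0.02, 0.08] at alpha = 0.05).
* **Bootstrap** (default 10,000): paired resampling; each resample's
  LVs aligned to the original by greedy correlation matching with sign
  flips (no Procrustes — L is small). BSR = original salience /
  bootstrap SD, per *variable*: a per-variable ratio is the only
  reading that yields the component-level bar plots this analysis
  produces; dividing the singular value by an SE would give one number
  per LV, not per component. Behavior loadings are reported as
  correlations between each variable and the brain latent score, with
  percentile CIs.
* Under a true null the alignment step is arbitrary and BSR dispersion
  inflates to ~1.2-1.4; in the coupled regime where BSRs are read, the
  false-flag rate for uncoupled components stays near nominal. The
  tests encode exactly this.

## 7. Molecular association

`dominance()` computes general dominance exactly for up to 20
predictors by enumerating all `2^q - 1` submodels from a precomputed
correlation matrix (each subset solved by Cholesky; the 19-predictor
panel's 524,287 models take seconds in the compiled path), falling back
to stratified subset sampling beyond. Dominances are computed on, and
sum exactly to, R² — the dominance identity holds for R², not adjusted
R² — while the headline fit is reported as adjusted R²; percent
contributions are shares of R².

`spatial_null_test()` compares the observed adjusted R² with that of
variogram-matched surrogates of the *component map* (randomizing the
map, not the predictors — the standard choice, and the alternative is a
one-line swap), with BH-FDR across the component family.

`distance_dependent_cv()` trains on the nearest 25% of regions to each
source region (as the procedure is defined — training on the *near*
fraction) and tests on the rest; one pass over all regions by default.

## 8. Surrogate maps

`generate_surrogates()` re-implements variogram-matched surrogate
generation at desk scale: permute the map, smooth with Gaussian
distance-decay kernels over a log-spaced bandwidth grid (quarter of the
median nearest-neighbour distance up to the variogram truncation
distance, 16 bandwidths), scale-and-offset each candidate so its
variogram matches the target's, and keep the candidate with minimum
realized variogram SSE; by default values are then rank-mapped onto the
original multiset so the null preserves the map's histogram exactly.

Numerical choices that matter with only 82 regions:

* **Equal-count distance bins** (25 bins to the 25th-percentile
  truncation distance) — equal-width bins starve at long range.
* **The target variogram is loess-smoothed** (span 0.75) before
  matching: individual bins average a few dozen pairs and are noisy;
  chasing them selects under-smoothed surrogates and mis-calibrates the
  null. With the smoothed target, null p-values are
  KS-indistinguishable from uniform and surrogates beat plain
  permutations on variogram SSE for the overwhelming majority of
  draws — both checked by the acceptance tests.
* **Selection on the realized candidate** (after noise and rank
  mapping), not on the idealized fit, because the realized map is what
  enters the null distribution.

## 9. The synthetic generator: what it emulates, and what it does not

`simulate_cohorts()` builds: a two-site reference cohort (203 + 254,
ages 3-18) with planted additive and multiplicative site effects
(location -0.15/+0.12 residual SDs, scales 0.95/1.10 — both signs so
harmonization is identifiable), per-region baselines (CT ~ 2.3-3.0 mm;
SV at structure-typical mm³), fractional-polynomial age curves (default
powers (0.5, 2), amplitudes giving ~0.2 mm CT thinning across
childhood), sex offsets, a global thickness factor and TIV effects, and
Gaussian residuals (CT ~ 0.12 mm); and a patient cohort (187, ages
4-18) plus 108 controls at a third, unshifted site. Patient deviations
are planted as `-(W_true H_true)` scaled by the *base* residual SD —
negative, i.e. thinning/volume loss, so the nonnegativity transform is
exercised realistically, and expressed in RMSE units so deviation
z-scores recover them directly. `deviation_effect` (default 1 RMSE
unit; 0 plants nothing) sets the loading scale; lowering `noise_sd`
raises deviation SNR because the planted effect keeps its absolute
size. Behavior is a weighted sum of planted loadings plus noise with
MCAR missingness (default 15% per cell, thinning 187 subjects to a few
dozen complete cases; an MNAR option concentrates missingness in low
scorers, for probing how compliance-driven missingness could bias the
complete-case analysis). Molecular maps are Gaussian random fields with
exponential covariance `exp(-d/30mm)`.

What it does *not* emulate — and therefore what green tests do not
show: non-Gaussian residuals and outliers, scanner software drift
within site, spatially *correlated* measurement noise across regions,
age-by-site confounding, longitudinal structure, and any geometric
realism beyond mirrored ellipsoid-shell centroids. Passing recovery
tests demonstrate the machinery is correct under its own assumptions,
not that real epilepsy cohorts decompose into eight components.

## 10. Problem sizes used in the checks

The automated checks run the generator at the study's cohort sizes
(457/187/108) for calibration, recover planted factorizations at
82 x 187 with rank 8 and SNR 10 over ranks 2-12 with 5 splits, use 400
null datasets at 500 permutations for PLS calibration, 100-200
surrogates per map for the spatial nulls, and 10-20 seeds for
recovery-rate statements. These sizes were chosen so each property is
measured with enough replication to be stable while a full run of the
suite stays comfortably interactive; the defaults inside the package
(100 splits, 10,000 permutations/bootstraps, 1,000 surrogates) remain
at analysis scale.

## 11. Known limitations

* Exact FP power-pair identification is not achievable over a pediatric
  age span (Section 3); only the fitted curve is reliable.
* The opNMF update inherits projective NMF's lack of a descent
  guarantee; rank-to-rank error comparisons carry basin noise.
* Complete-case PLS with ~20% of subjects retained has the external
  validity of those subjects only; the MNAR generator option exists to
  probe exactly this.
* Surrogate matching at 82 regions is approximate by nature; with
  hundreds of parcels the variogram constraints tighten considerably.
* The region atlas is synthetic geometry; no surface-based (geodesic)
  distances are offered.
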