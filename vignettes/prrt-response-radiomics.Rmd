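---
title: "Predicting per-lesion PRRT response from somatostatin-receptor PET radiomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting per-lesion PRRT response from somatostatin-receptor PET radiomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petrad)
```

## The problem

Gastroenteropancreatic neuroendocrine tumors (GEP-NETs) expressing
somatostatin receptor 2 can be treated with peptide receptor radionuclide
therapy (PRRT), but a substantial minority of lesions progress despite
treatment, and conventional PET quantification (SUVmax, lesion volume) is a
poor predictor of which ones. `petrad` implements a per-lesion analysis
pipeline that asks whether the *shape of the intensity histogram* inside a
lesion on baseline somatostatin-receptor PET — in particular its skewness
and kurtosis — predicts progression after a complete PRRT course, and
whether the answer differs by anatomical district (liver, lymph node,
bone).

The unit of analysis is the lesion, not the patient: a cohort of a few
dozen patients yields a few hundred lesions, each with a binary outcome
(progressive disease vs any responsive outcome) determined from paired
baseline/follow-up imaging.

## The pipeline

1. **Imaging substrate.** A lesion is a binary voxel mask on an SUV volume.
   Masks with fewer than 16 voxels (about 0.443 mL at ~3 mm isotropic PET
   voxels) are excluded: co-occurrence statistics on smaller regions are
   too sparse to be meaningful.
2. **Discretization.** ROI intensities are mapped to 64 grey levels by
   *absolute* rescaling over the fixed window 0–60 SUV (bin width 0.9375
   SUV). Fixed bounds — rather than per-lesion min/max — make histogram
   shape comparable across lesions and scanners. Out-of-window values are
   clamped to the edge bins, so the mapping is total.
3. **Features.** Four families, prefixed `HISTO_`, `SUV_`, `SHAPE_`,
   `GLCM_`. Histogram skewness/kurtosis/entropy/energy are weighted moments
   over bin centers; kurtosis is **non-excess** (a Gaussian scores 3),
   which matches the magnitudes this field reports (district medians up to
   ~23). Conventional statistics use the raw, undiscretized SUVs. Shape
   volume is voxel count times voxel volume; sphericity uses face-counted
   surface area. The GLCM is symmetric, distance 1, 13 3-D directions,
   normalized per direction with features averaged over directions.
4. **Labeling.** Per lesion: disappearance at follow-up is CR; a ≥25 %
   increase in longest diameter *or* SUVmax is PD; a ≥25 % decrease in
   either is PR; otherwise SD. The dichotomous outcome codes PD as 0 and
   SD/PR/CR as 1. Delta-radiomics is the percent change
   `100·(T1 − T0)/T0`, reported missing (never infinite) when the baseline
   value is 0.
5. **Selection.** Features are ranked by the absolute point-biserial
   correlation with the outcome; forward logistic regression adds one
   ranked feature at a time and stops at the first increase of the
   monitored p-value (see below).
6. **Classification.** Linear discriminant analysis (class-conditional
   Gaussians, pooled covariance) on the retained features, evaluated with
   stratified 5-fold cross-validation; every lesion is scored exactly once,
   out of fold, with the posterior probability of the non-responder class.
7. **Evaluation.** Empirical ROC over all distinct scores; trapezoidal AUC
   (identical to the normalized Mann–Whitney U statistic); Youden-index
   cut-off with ties broken toward higher sensitivity. The positive class
   for sensitivity is the **non-responder** (PD) lesion: cut-offs flag
   progression.

## Design choices where the design was open

**Bin width 0.9375 vs 0.95.** The window/bins parameterization (0–60 SUV,
64 bins) implies a width of 0.9375; the legacy extraction convention also
quotes 0.95. The bounds-plus-bins form is primary here because it is
internally consistent; `disc_config(bin_width = 0.95)` restores the
alternative, with the last bin absorbing the remainder.

**Which p-value the forward selection monitors.** The procedure is
specified only as "logistic regression … stopping in the case of a growing
p-value". Three readings are implemented (`p_mode` in `forward_select`):

* `"lrt"` (default): the model-vs-intercept likelihood-ratio p. It is the
  only p-value defined at every multi-feature step, and it reliably
  recovers jointly informative features (two d = 1 features at n = 300 are
  both retained in essentially every replicate).
* `"inc"`: the 1-df model-vs-previous LRT.
* `"wald"`: the newest coefficient's Wald p.

These behave very differently on *null* data. Because features enter in
|pbc| order, the first candidate's apparent association is the maximum of
~50 noise correlations, and under `"lrt"` the cumulative chi-square keeps
growing faster than the per-step df penalty for several steps — so on
label-permuted data the default rule usually retains more than one noise
feature. The 1-df readings stop almost immediately on nulls, but for the
same ordering reason they essentially never admit a second *informative*
feature (the stronger one enters first, so the 1-df p-sequence increases
by construction). No single monitored p-value gives both good null
behavior and multi-feature recovery; the package defaults to `"lrt"`
(multi-feature recovery, matching the published three-feature model) and
treats the retained set as descriptive, not inferential. The acceptance
suite asserts both properties for the default rule and the null half is
an honest failure.

**Sorting by |pbc|.** Negative correlations are as informative as positive
ones (the outcome codes response as 1 while the predictive histogram
features are *higher* in non-responders); `sort_mode = "signed"` restores
literal descending order.

**PD precedence.** When size and SUVmax changes conflict (one up ≥25 %,
one down ≥25 %), the lesion is classified PD: a progression-dominant,
clinically conservative reading of the "either criterion" rule.

**Clinical covariates.** Grading enters as ordinal numeric 1/2/3;
chromogranin A values are `log(1+x)`-transformed (right-skewed lab
values). Post-therapy CgA is accepted as a column but excluded from the
default predictor set because it post-dates the treatment being
predicted; `prepare_clinical(include_cga_post = TRUE)` restores it.

**Single-feature ROC orientation.** Raw features are used directly as
scores, negated when their point-biserial correlation says higher values
track response, so that a higher score always means "more likely
non-responder". Per-site reports keep the legacy "AUC < 0.5 ⇒ not
informative" flag but also print `1 − AUC`, since a below-chance AUC
usually just signals an inverted orientation.

## The synthetic world

No patient data are distributed, so the package carries generators for
every input, plus machine-readable copies of the published summary tables
(`paper_fixtures()`, `table2_params()`).

* **Voxel-level lesions** (`synth_lesion_volume`): an ellipsoidal mask
  with an exact voxel count inside a zero background, filled with a
  moment-matched shifted lognormal (mirrored for negative skewness,
  normal at skewness ≈ 0) clipped to the 0–60 SUV window. Targets are the
  mean, SD and skewness of the raw intensities; kurtosis then follows the
  lognormal skewness–kurtosis relation and is only checked for
  feasibility (kurtosis ≥ skewness² + 1). Default SD is mean/4 — a
  moderate heterogeneity typical of receptor-PET lesions that keeps the
  distribution inside the window.
* **Feature cohorts** (`sample_feature_cohort`): per-district, per-group
  normal draws using the published "median ± DS" values as location/scale
  and the published group sizes (lymph node 50/41, liver 108/61, bone
  18/24 responders/non-responders), plus independent standard-normal
  noise features. Treating printed medians as means is an approximation;
  its adequacy is *demonstrated*, not assumed: the analytic two-Gaussian
  AUC `Φ(|μ₁−μ₀|/√(σ₁²+σ₀²))` of those parameters reproduces the
  published per-district AUCs within a few hundredths (bone skewness
  0.730 vs 0.73 printed), and the acceptance suite confirms it by
  simulation.
* **Paired cohorts** (`sample_paired_cohort`): `T1 = T0·(1 + Δ/100)` with
  Δ drawn per group from configurable normal shifts (the published delta
  tables by default), so `delta_feature` recovers the drawn Δ exactly.

What the generators deliberately do **not** emulate: PET physics (PSF,
reconstruction noise texture), inter-feature correlation between skewness
and kurtosis (default 0; they are strongly dependent in real lesions),
scanner heterogeneity, and within-patient lesion clustering. A green test
therefore establishes that the *statistical machinery* reproduces what
the stated location/scale world implies — not that the published effect
sizes would replicate in new patients.

## Numerical choices and degenerate inputs

* Zero-spread histograms: skewness/kurtosis are `NA`, never 0; selection
  drops features missing in any lesion and logs it.
* GLCM on a constant ROI: energy 1, entropy 0, correlation `NA` (zero
  marginal variance). Directions with no in-mask pair are skipped;
  features average over populated directions only.
* Mann–Whitney: exact p (via the exact U distribution) when there are no
  ties and min(n₁,n₂) ≤ 8; otherwise a tie-corrected normal approximation
  with continuity correction. Exhaustively at n = 8/8 the worst-case gap
  between the two is 0.0109 — a uniform 0.01 agreement is not attainable
  by any standard normal approximation at such sizes.
* Singular pooled covariance in the discriminant: regularized once by a
  scaled identity with a warning; a still-singular matrix is a hard error.
* Youden ties: the lowest maximizing threshold (highest sensitivity).
* All randomness (generators, fold assignment) flows from explicit integer
  seeds; generator calls restore the caller's RNG state.

## Known limitations

* Face-counted surface area overestimates smooth boundaries by up to 1.5×,
  so digital-sphere sphericity converges to ~2/3 rather than 1; sphericity
  values are comparable within this convention only.
* The feature set covers every family the analysis relies on (~20
  features) but is not a bit-exact reimplementation of the 65-feature
  legacy extraction.
* Selection is performed on the full table before cross-validation
  (matching the published sequential design), which leaks selection
  information into the CV estimate; a leakage-free nested mode is the
  obvious extension.
* Masks must be defined on the PET grid; no registration or resampling is
  performed between timepoints.
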