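# petrad

Per-lesion radiomics analysis of somatostatin-receptor PET for predicting
response to peptide receptor radionuclide therapy (PRRT).

## What it does, and for whom

In metastatic gastroenteropancreatic neuroendocrine tumors treated with
PRRT, a sizeable fraction of lesions progress despite therapy, and
conventional PET quantification (SUVmax, lesion volume) predicts this
poorly. `petrad` is aimed at nuclear-medicine and imaging-statistics
researchers who want a tested, reproducible implementation of the
per-lesion "radiomics → response" workflow:

* fixed-bound intensity discretization of lesion SUVs (0–60 SUV, 64 bins)
  and first-order histogram features — skewness and kurtosis of the
  discretized histogram are the workhorse predictors;
* conventional (SUVmin/mean/max/std, MTV, TLG), shape, and GLCM texture
  features;
* per-lesion response labels from paired baseline/follow-up measurements
  (PD / SD / PR / CR via a ±25 % size-or-SUVmax rule), dichotomized as
  progression (0) vs any response (1);
* point-biserial ranking + forward logistic selection with a growing-p
  stopping rule;
* linear discriminant classification, stratified 5-fold cross-validation,
  ROC/AUC and Youden cut-offs (positive class = non-responder);
* delta-radiomics (`Δ = 100·(T1 − T0)/T0`) and per-district (liver, lymph
  node, bone) sub-analyses;
* a calibrated synthetic-data generator for every input, since no patient
  data are distributed.

The core statistic connecting the synthetic world to published results is
the two-Gaussian ROC identity: for class-conditional feature distributions
N(μ₁, σ₁²) and N(μ₀, σ₀²), the single-feature AUC is
Φ(|μ₁ − μ₀| / √(σ₁² + σ₀²)). Feature cohorts sampled from the embedded
per-district location/scale tables reproduce the published district AUCs
to within a few hundredths.

## Worked example

```r
library(petrad)

# a surrogate cohort: 302 lesions across lymph node / liver / bone with
# the published per-district group sizes, plus 5 noise features
tab <- sample_feature_cohort(cohort_spec(n_noise = 5, seed = 7))
out <- run_pipeline(tab, pipeline_config(seed = 7))
out$selection
#> <selection_result> retained 2 feature(s): HISTO_Skewness, HISTO_Kurtosis
#>   p-trace (lrt): 1.53e-14 -> 4.77e-22 -> 2.79e-21
out$roc
#> <roc_result> AUC 0.812; Youden cut-off 0.3873 (sens 81.7%, spec 71.6%)
```

Selection keeps the two histogram-shape features and discards the noise;
the cross-validated discriminant separates progressive from responsive
lesions with AUC 0.81 on this draw (the cut-off is on the posterior
probability of progression; sensitivity is the fraction of progressive
lesions flagged). The bone sub-analysis shows the district-level signal:

```r
ps <- out$per_site$bone$comparisons
ps[ps$feature == "HISTO_Skewness", c("feature", "median_responder",
                                     "median_nonresponder", "U", "p")]
#>          feature median_responder median_nonresponder   U            p
#> 1 HISTO_Skewness         2.381511            3.954651 355 0.0004312616
```

Non-responding bone lesions have visibly higher histogram skewness. A
voxel-level phantom exercises the full extraction path:

```r
les <- synth_lesion_volume(lesion_spec(n_voxels = 2000, mean_suv = 10,
                                       skewness = 2.45, seed = 7))
fv <- extract_features(les$volume, les$roi)
round(fv[c("HISTO_Skewness", "HISTO_Kurtosis", "SUV_max", "MTV",
           "GLCM_Entropy")], 3)
#> HISTO_Skewness HISTO_Kurtosis        SUV_max            MTV   GLCM_Entropy
#>          2.488         13.564         33.091         54.000          6.074
```

The extracted histogram skewness (2.49) sits near the generator target
(2.45); MTV is exactly 2000 voxels × 27 mm³ = 54 mL.

A command-line front end is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts/petrad.R", package = "petrad"))') \
  simulate --mode cohort --seed 3 --out sim/
```

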