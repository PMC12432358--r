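# methrisk

Blood DNA methylation carries prognostic information about cardiovascular
complications of type 2 diabetes. **methrisk** implements, as a tested and
reusable R pipeline, the statistical workflow for discovering and evaluating
blood-based methylation biomarkers of incident macrovascular events
(myocardial infarction, angina, ischemic heart disease, stroke) in newly
diagnosed type-2-diabetes cohorts:

1. **Weighted survival EWAS.** For each CpG site, a weighted Cox
   proportional-hazards model (Breslow ties, Newton-Raphson on the weighted
   partial likelihood) relates the site's M-value — standardized to unit SD,
   so hazard ratios are *per 1 SD of methylation* — to time-to-event,
   adjusted for clinical covariates (model 1: age, gender, BMI, HbA1c;
   further models add medications, the smoking-proxy methylation of
   cg05575921, lipids, cell-composition estimates). Sampling weights
   (cohort/sample stratum ratios) account for case-control sampling into the
   analysis set.
2. **Site selection.** Benjamini-Hochberg FDR < 0.05 in the discovery model,
   nominal p < 0.05 across all adjustment models, and an absolute
   beta-scale group difference (delta-beta) of at least 2%.
3. **Methylation risk score.** MRS_i = sum over selected sites of
   (log HR per SD) x (standardized M-value), i.e. a Cox-coefficient-weighted
   methylation sum score.
4. **Cross-validated risk prediction.** Weighted logistic regression
   (weights = sampling x inverse-probability-of-censoring weights, the
   latter from a Kaplan-Meier estimate of the censoring distribution) under
   stratified 5-fold cross-validation, for three models: MRS alone, clinical
   risk factors alone, and their combination.
5. **Evaluation.** ROC/PR curves, DeLong AUC comparison, Youden-index
   screening cutoff, prevalence-based PPV/NPV/accuracy, categorical and
   continuous net reclassification improvement (NRI) and integrated
   discrimination improvement (IDI), and Kaplan-Meier / log-rank /
   weighted-Cox stratification of the dichotomized risk.

Because real cohort methylation data of this kind is access-restricted, the
package ships a **synthetic cohort generator** (`simulate_cohort()`) that
reproduces the statistical structure of such a study — 752 subjects, ~13.6%
incident events within 7.2 years of administrative follow-up, per-site
beta-values with SD 0.05, planted per-SD log-hazard effects, realistic
covariate distributions — so every stage of the pipeline is testable
end-to-end with known ground truth.

## Worked example

```r
library(methrisk)

sim <- simulate_cohort(sim_config(n_sites = 300, seed = 42))
sim
#> Synthetic cohort: 752 subjects, 300 sites, 103 events (13.7%)
#> causal sites: 10, baseline hazard 0.006251/year

pl <- mrs_pipeline(sim$methylation, sim$phenotypes, seed = 42)
pl
#> MRS pipeline (paper mode)
#> selected sites: 7
#> cross-validated AUC: MRS 0.882 | clinical 0.527 | MRS+clinical 0.877
#> DeLong p (MRS+clinical vs clinical): 1.08e-30
#> Youden cutoff 0.166 (sens 0.883, spec 0.749)
#> Risk strata: n_low = 498, n_high = 254
#> log-rank chi2 = 176.87, p = 2.34e-40
#> weighted-Cox HR (high vs low) = 18.88 (95% CI 10.33-34.50), p = 1.31e-21
```

Reading the output: of 300 simulated sites (10 causal), 7 pass the
FDR + robustness + delta-beta selection and form the MRS. Pooled
out-of-fold predicted risks give an AUC of 0.88 for the MRS-containing
models against 0.53 for clinical covariates alone (this cohort plants no
strong clinical effects). The Youden cutoff on the combined model splits
the cohort into 498 low-risk and 254 high-risk subjects whose event-free
survival separates sharply.

The screening arithmetic is available directly; for a test with
sensitivity 0.804 and specificity 0.728 in a cohort of 102 events and 650
controls:

```r
screening_metrics(0.804, 0.728, n_events = 102, n_controls = 650)
#> Screening test report
#>   sensitivity: 80.4%   specificity: 72.8%
#>   TP 82  FN 20  TN 473  FP 177
#>   prevalence:  13.6%
#>   PPV 31.8%  NPV 95.9%  accuracy 73.8%
```

A screening test this sensitive still has a modest PPV at 13.6%
prevalence — Bayes' rule at work — while the NPV of 95.9% makes a negative
result highly informative.

## Package layout

- `R/synthetic_cohort.R` — cohort generator and power calculation
- `R/methylation_data.R` — matrix/phenotype I/O, beta/M conversions,
  probe masks
- `R/ipw_weights.R` — sampling weights, Kaplan-Meier estimator, censoring
  weights
- `R/weighted_cox.R`, `R/ewas.R` — weighted Cox fitter and per-site scan,
  FDR, robustness and effect-size filters
- `R/tissue_stats.R` — paired t-tests with FDR, Spearman
  methylation-expression association
- `R/mrs.R`, `R/cv_predict.R` — risk score and cross-validated weighted
  logistic prediction
- `R/roc.R`, `R/strata.R`, `R/pipeline.R` — evaluation metrics, survival
  stratification, end-to-end driver
- `vignettes/methylation-risk-pipeline.Rmd` — the methods vignette
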