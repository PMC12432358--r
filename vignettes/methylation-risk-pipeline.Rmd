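---
title: "Methylation risk prediction for macrovascular events: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation risk prediction for macrovascular events: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Newly diagnosed individuals with type 2 diabetes differ widely in their risk
of a first macrovascular event — myocardial infarction, angina, ischemic
heart disease or stroke — and clinical risk factors discriminate only
moderately between those who will and will not have one. Blood DNA
methylation offers a minimally invasive biomarker substrate: each CpG site
on a methylation array yields a *beta-value*, the methylated fraction in
[0, 1], and its logit2 transform, the *M-value*
$M = \log_2\!\big(\beta/(1-\beta)\big)$, which is unbounded and better
behaved for modelling. **methrisk** implements the full path from a sites ×
samples methylation matrix plus a phenotype table to an evaluated screening
test, with a synthetic cohort generator standing in for access-restricted
real data.

# Models and procedure

## Inverse-probability weights

Two weight sets enter the analysis, and they deliberately enter different
stages:

* **Sampling weights** $W_{samp}$ correct for case-control sampling of the
  analysis set from a larger source cohort: every case is weighted by
  (cohort cases)/(sampled cases), every control by the control ratio. With
  full sampling all weights are 1.
* **Censoring weights** $W_{cens}$ make the *binary* end-of-study outcome
  analyzable by logistic regression despite censoring. The probability of
  remaining uncensored, $G(t)$, is estimated by a Kaplan-Meier estimator
  with censoring treated as the event; administrative end of follow-up does
  not count as censoring. A subject with an event at $T$ receives
  $1/G(T^-)$, a subject followed event-free to the horizon receives
  $1/G(\tau^-)$, and a subject censored event-free earlier receives 0 (a
  flag retains them at $1/G(C^-)$ instead). This redistributes each
  censored subject's mass among those still at risk; with the tie rule
  "events precede censorings" the weighted event frequency reproduces the
  Kaplan-Meier event probability at the horizon *exactly*, which the test
  suite asserts to 1e-6. $G$ is floored at 0.05 (configurable), capping
  weights at 20 for variance control.

The Cox stage uses $W_{samp}$ only — the partial likelihood handles
censoring itself — while the logistic stage uses
$W_{final} = W_{samp} \times W_{cens}$.

## Per-site weighted Cox EWAS

For site $s$ the model is a weighted Cox proportional-hazards regression
with the site's M-values standardized to zero mean and unit SD, so the
reported hazard ratio is per 1 SD of methylation, plus adjustment
covariates. The weighted Breslow log partial likelihood

$$\ell(\beta) = \sum_{i:\delta_i = 1} w_i x_i'\beta -
  \sum_t W_t \log \sum_{j: T_j \ge t} w_j e^{x_j'\beta}$$

is maximized by Newton-Raphson with step halving (convergence when the
largest score component falls below 1e-8, at most 50 iterations);
standard errors come from the inverse observed information and p-values
are Wald. The fitter agrees with `survival::coxph(ties = "breslow")` to
1e-6 (coefficients and naive SEs), and integer weights reproduce subject
duplication to 1e-8 — both frozen as tests. Sites where the fit fails
(separation, flagged at |coef| > 20, or non-convergence) are carried as
flagged rows rather than aborting a genome-wide scan.

Design choices worth making explicit:

* **Breslow ties**, because it is exact under weights and simple; with
  survival times on a continuous scale ties are rare anyway.
* **Unweighted per-site SD** for standardization. Whether a weighted SD
  was intended is unknowable from the outside; the unweighted choice is
  deterministic and documented.
* **Group means and delta-beta on the beta scale** (events minus
  controls), because methylation differences are conventionally reported
  in percentage points of methylation.

## Selection, score, prediction

Sites are selected by (1) Benjamini-Hochberg q < 0.05 in the discovery
model, (2) optionally p < 0.05 in every supplied adjustment model
(robustness screen), (3) |delta-beta| >= 2%, inclusive at the boundary.
The 2% floor discards statistically significant but minute differences
that would be unlikely to replicate or to survive assay noise.

The methylation risk score is
$MRS_i = \sum_s \hat\beta_s \, z_s(i)$ with $\hat\beta_s$ the site's log
hazard ratio per SD and $z_s$ the standardized M-value, using the
*training* standardization when scoring new samples — so the score is
invariant to constant shifts of a site and deterministic given the model.

Predicted risks come from weighted logistic regression (IRLS; deviance
change < 1e-8, at most 100 iterations; a ridge fallback with penalty 1e-6
catches separation) under stratified 5-fold cross-validation. Folds
stratify jointly on event status and gender, falling back to event-only
stratification with a warning when a cell is smaller than k. Censoring
weights are recomputed within each training fold, since they are
functions of the training data's censoring distribution.

Two pipeline modes differ in where selection happens:

* **paper mode** (default): sites are selected and the MRS coefficients
  fitted on the full data; only the logistic stage is cross-validated.
  This mirrors the common EWAS-then-CV design and is the mode whose
  outputs the defaults report.
* **nested mode**: selection and MRS fitting are repeated inside each
  training fold. This is the honest generalization estimate. On a fully
  null synthetic cohort, paper mode's pooled MRS AUC sits near 0.65-0.70
  purely from selection leakage while nested mode stays at 0.5 — the test
  suite asserts the ordering, and anyone interpreting paper-mode AUCs on
  real data should keep that gap in mind.

## Evaluation

The empirical ROC uses the rule "positive if predicted risk > t" over all
observed thresholds; the trapezoid AUC then equals the Mann-Whitney
statistic (ties at 1/2), an identity the tests check exactly, including
under per-sample weights. AUCs of the combined and clinical-only models
are compared with DeLong's test for paired ROC curves (via `pROC`, the
standard tool for this), chosen because no specific test is implied by
the design; identical predictions return p = 1.

The screening cutoff maximizes the Youden index
$J = \text{sens} + \text{spec} - 1$, ties broken toward the lower cutoff.
`screening_metrics()` expands an operating point into confusion counts
(rounded half away from zero) and Bayes-rule PPV/NPV/accuracy. The
Bayes-rule metrics are evaluated at the prevalence rounded to 0.1% — the
precision at which screening reports quote prevalence — so the printed
percentages are mutually consistent at one-decimal precision; with
sensitivity 0.804 and specificity 0.728 at 102/650 this yields PPV 31.8%,
NPV 95.9%, accuracy 73.8%.

Reclassification uses the standard estimators: categorical NRI over two
risk categories split at the chosen cutoff, continuous NRI over any risk
movement, and IDI as the difference in discrimination slopes, each with
asymptotic SEs and Wald CIs. Finally the cohort is dichotomized at the
cutoff (strictly greater than; the boundary is the last "negative"
value), and separation quantified by per-group Kaplan-Meier curves, the
unweighted log-rank test, and a weighted-Cox hazard ratio of high vs low
(weights again $W_{samp}$ only).

# The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the analysis
assumes, with defaults frozen to the study conditions of a prospective
newly-diagnosed type-2-diabetes cohort:

| parameter | default | rationale |
|---|---|---|
| `n_subjects` | 752 | cohort size |
| `target_event_fraction` | 0.136 | observed incident-event fraction |
| `admin_censor_years` | 7.2 | administrative end of follow-up |
| `random_censor_rate` | 0.17 /year | gives mean event-free follow-up ≈ 3.9 y and mean time-to-event ≈ 2.0 y |
| `site_beta_sd` | 0.05 | typical per-site beta-value SD |
| `site_beta_mean_range` | (0.1, 0.9) | covers hypo- to hypermethylated sites |
| `n_causal_sites`, `causal_log_hr_per_sd` | 10, 0.7 | per-SD hazard ratios ≈ 0.5-2, the magnitude range reported for MRS sites |
| `covariate_effects` | age: 0.3 /SD | a moderate age effect (marginal AUC ≈ 0.6) |

Methylation is generated per site as Gaussian on the M scale and
transformed to beta; the M-scale SD is set by the delta method,
$\sigma_M = \sigma_\beta / (\ln 2 \cdot \mu_\beta(1-\mu_\beta))$, so the
realized beta-scale SD tracks 0.05. Event times follow an exponential
baseline hazard under proportional hazards with linear predictor
$\sum_s \beta_s z_s + \text{covariate terms}$; causal effects are planted
in both directions in equal proportion (the direction balance of real
discovery sets is an empirical outcome, not imposed). Observed time is
the minimum of event time, exponential random censoring and the
administrative cutoff. The baseline hazard is calibrated to the target
event fraction by 20 bisection steps on the cohort's own uniform draws,
making the whole cohort a deterministic, byte-identical function of the
seed.

What the generator does **not** emulate: array intensities and detection
noise, batch and chip effects, cell-composition mixtures, correlated CpG
blocks, genotype-driven (SNP-like) methylation patterns, and two-cohort
structure. Passing tests on synthetic data therefore demonstrate the
statistical machinery — calibration, recovery, weighting identities,
leakage behavior — not robustness to array artifacts.

A closed-form power helper accompanies the generator:
`power_two_sample()` gives the symmetric two-sided normal-approximation
power for a difference of means, which evaluates to 0.96 for a 2%
methylation difference at SD 0.05 with 650 vs 102 subjects, and exactly
to alpha under the null — the two-tail form is used precisely so the null
case is exact.

# Numerical and degenerate-input policy

* Beta-values at exactly 0 or 1 are clipped to 1e-6 before the logit2
  transform; whole-matrix conversion round-trips to 1e-10.
* Missing methylation values are not permitted after loading; the loader
  drops any site with a missing value (complete-case Cox fits stay
  comparable across sites).
* Matrix I/O uses one fixed dialect (comma-separated, decimal point,
  mandatory header, probe IDs first) and writes at full double precision;
  round-trips are exact to 10 significant digits.
* Zero-variance sites, constant covariates, one-class outcomes, empty
  strata and all-masked matrices raise typed errors naming the offending
  site/field; per-site scan failures are flagged rows, not exceptions.
* A paired t statistic with zero difference variance is 0 (p = 1) when
  the mean difference is 0 and unbounded (p = 0) otherwise.
* Ties between an event and a censoring at the same time: the event
  precedes the censoring, in the survival KM, the censoring KM and the
  weight construction alike.

# Problem sizes used in the checks

The shipped tests and the acceptance script run at sizes chosen to
exercise the asymptotic regimes the methods rely on while staying
desk-sized: null-calibration scans use 1000 sites at n = 800 (~100
events); the Benjamini-Hochberg null-discovery property uses 40
independent cohorts of 500 sites at n = 400 (~54 events — below that, the
Wald far-tail at a few dozen events is visibly anticonservative and the
check would measure small-sample artifacts rather than the FDR
procedure); parameter recovery uses n = 2000; the discrimination
comparison uses 20 cohorts of 300 sites at n = 752. The end-to-end
example in the README uses 300 sites so the whole pipeline runs in
seconds.

# Known limitations

* Sites are scanned independently; no shrinkage or correlation-aware
  inference across CpGs.
* The censoring-weight scheme targets a fixed-horizon binary endpoint;
  competing risks and time-varying effects are out of scope.
* Confidence intervals for AUCs are not provided (DeLong p-values for
  paired comparisons only); NRI/IDI inference is asymptotic, not
  bootstrap.
* Cell-composition covariates are accepted as numeric phenotype columns;
  the deconvolution that produces them is outside the package.
* Paper-mode cross-validation inherits the selection leakage discussed
  above by design; use nested mode for unbiased performance estimates.
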