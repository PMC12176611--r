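---
title: "Evaluating two-cutoff blood-biomarker triage: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating two-cutoff blood-biomarker triage: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Plasma phospho-tau217 (p-tau217) discriminates patients with underlying
Alzheimer's disease (AD) pathology from other causes of cognitive symptoms
well enough to be used as a first-line test in memory clinics and primary
care. Because no single threshold is simultaneously sensitive and specific
enough for a stand-alone diagnosis in every setting, a *two-cutoff* (triage)
rule is attractive: patients below a lower cutoff are called negative, above
an upper cutoff positive, and those in between — the *intermediate* or gray
zone — are referred for confirmatory CSF or amyloid-PET testing.

`adtriage` implements the complete evaluation machinery for this design:

1. a reference standard for AD pathology derived from the CSF
   Aβ42:p-tau181 ratio by two-component Gaussian mixture modeling (with an
   amyloid-PET visual-read fallback for subjects without CSF);
2. cutoff derivation on a derivation cohort — a single cutoff at 90%
   specificity, a dual pair at 95% sensitivity / 95% specificity, and a
   Youden-index alternative — each reported as the mean of 2,000 bootstrap
   replicates with a percentile confidence interval;
3. classification and performance metrics under the intermediate-exclusion
   rule, with percentile bootstrap CIs;
4. statistical comparisons: DeLong tests for AUCs and a recentred bootstrap
   hypothesis test for accuracy/PPV/NPV differences, applied to markers,
   care levels and demographic/comorbidity subgroups;
5. a per-patient cost model for blood-test-first triage; and
6. a calibrated synthetic-cohort generator, so that every stage is testable
   end to end: the clinical cohorts this methodology is used on are only
   available on request, so the generator is a first-class, tested component
   rather than a fixture.

# The synthetic cohort model

## Class-conditional log-normals, calibrated by moment matching

Within each AD-pathology class, marker concentrations are modelled as
log-normal — concentrations are positive and right-skewed, and published
cohort summaries (pooled SD of the same order as the pooled mean) are
consistent with heavy right skew. The two classes share a log-scale SD
$\sigma$, so the AUC of the marker has the closed form

$$\mathrm{AUC} = \Phi\!\left(\frac{\mu_+ - \mu_-}{\sigma\sqrt{2}}\right),$$

which `lognormal_mixture_calibrate()` inverts: given a cohort's pooled mean
and SD, its AD prevalence $\pi$, and a target AUC, it solves for
$(\mu_-, \mu_+, \sigma)$ such that the two-component mixture reproduces the
pooled moments exactly and the class separation yields the target AUC. The
five built-in cohorts use the published sizes, prevalences, pooled plasma
p-tau217 moments, age/education distributions, sex/APOE/stage mixes, and
target AUCs chosen once within the published 0.93–0.96 range (0.95, 0.96,
0.95, 0.93, 0.93 for Malmö, Gothenburg, Barcelona, Brescia and Swedish
primary care respectively; the derivation cohort and the
highest-performing secondary care cohort sit near the top of the range,
the high-comorbidity cohorts at the bottom).

## Covariate effects

Multiplicative shifts act on the marker level: chronic kidney disease (CKD,
eGFR < 60 ml/min/1.73 m²) elevates blood tau in both classes (default
×1.25); age lowers plasma p-tau217 in AD-positive subjects and raises it in
AD-negative subjects (bands <73, 73–80, ≥80 years; defaults 1/0.85/0.72 and
1/1.12/1.25); women with AD pathology run slightly higher (×1.12). CKD acts
equally on plasma p-tau217 and plasma Aβ42, so the p-tau217:Aβ42 ratio is
CKD-insensitive; the mass-spectrometry (MS) markers carry only the CKD
effect, which cancels in %p-tau217 (p-tau217:np-tau217 × 100). These
defaults reproduce, qualitatively, the reported robustness ordering of the
ratio markers.

Two technical points keep the calibration exact in the presence of these
effects. First, multipliers are recentred to expectation 1 within each
class, so class-conditional means are untouched. Second, the variance the
multipliers add on the log scale is subtracted from the residual noise, so
the total class-conditional log-variance stays at the calibrated
$\sigma^2$ and the target AUC is preserved (the residual variance is
checked to stay positive). Covariate effects therefore redistribute
discrimination across strata — older bands lose separation, mirroring the
reported age effect — without changing the marginal calibration.
`cohort_moments()` returns the exact analytic moments implied by a
parameter set, mixing over classes and covariate strata, and the test suite
checks the generator against them at n = 50,000.

## Correlation, reference markers, and missingness

A single latent "pathology burden" factor with loading 0.8 (configurable)
induces within-subject correlation across markers; no inter-assay
correlations are published, so this default is a stand-in and is flagged
as such. The CSF Aβ42:p-tau181 ratio is generated from two well-separated
components (AD-negative mean 33, SD 9; AD-positive mean 6, SD 1.5). The
separation is deliberate: in the study design the CSF ratio *defines* the
reference standard, so the generator keeps disagreement between the
mixture-derived label and the generating class at ~0.5% — enough to
exercise the mixture fit, but without injecting reference-label noise that
the construct being emulated does not have. The same reasoning gives
subjects without CSF (a configurable fraction of primary care, default
87/548) a PET visual read equal to the generating label: the study treats
the visual read as reference standard, not as a noisy test. All other
fields are complete, matching the reported absence of missing plasma
values.

The generator draws covariates independently of the AD class (only marker
levels depend on class). Real cohorts couple stage and prevalence — the
dementia stratum has more AD pathology — so stage-wise PPV/NPV gradients
driven by differential prevalence are *not* emulated; stage subgroup
machinery is still exercised, but on equal-prevalence strata.

# The reference standard

`fit_gmm_cutoff()` fits a univariate two-component Gaussian mixture by EM
(free weights, unequal variances) and returns the equal-posterior point
between the component means — the standard way to dichotomize a bimodal
biomarker without external labels. Numerical choices:

* **Scale.** The fit is on raw ratios by default (the conventional cutoff
  is quoted on the raw scale); a `log_scale` switch is provided.
* **Initialization.** A split at the median plus 10 random quantile splits,
  keeping the best final log-likelihood; all randomness is seed-controlled.
* **Convergence.** Relative log-likelihood change below 1e-12, up to 5,000
  iterations; non-convergence is flagged (or raised on request).
* **Degeneracy.** Component SDs are floored at 1e-8 of the data SD and
  collapsing weights abort that restart; if the two fitted means coincide
  (within 1e-6 pooled SD) the fit is declared non-identifiable and no
  cutoff is returned, rather than an arbitrary root.
* **Cutoff.** The equal-posterior equation is a quadratic in $x$; the root
  between the component means is returned (closed form, with the linear
  equal-variance special case handled).

Label assignment uses strict `<` for Aβ42:p-tau181 positivity and `≤` for
the secondary Aβ42:40 outcome (fixed cutoff 0.072), copying the published
boundary conventions; subjects without CSF take the PET read when the
fallback is enabled, and are `"unknown"` otherwise.

# Cutoffs

`empirical_cutoff()` scans candidate thresholds — midpoints between
consecutive distinct observed values with ±∞ sentinels, the common ROC
convention — under the rule *positive iff value > cutoff*. At-specificity
returns the threshold with specificity ≥ target and maximal sensitivity;
at-sensitivity symmetrically; Youden maximizes sens + spec − 1. All ties
break toward the higher-specificity threshold, consistent with the
specificity-first philosophy of the single cutoff (configurable behavior
was considered and rejected to keep derivations reproducible). The scan is
implemented with cumulative counts over the sorted distinct values
(O(n log n)); the test suite checks it against an exhaustive per-candidate
scan.

`bootstrap_cutoff()` resamples subjects with replacement (unstratified —
no stratification is described for the published procedure), derives the
empirical cutoff per resample, and reports the **mean of the bootstrap
cutoffs** as the point estimate with the 2.5th/97.5th percentile interval.
Resamples that lose a class are redrawn (bounded at 100 × n_boot
attempts). Whether the achieved operating points should be evaluated
before or after taking the bootstrap mean is unspecified in the published
design; both are reported (`empirical_cutoff` and `achieved_sens`/
`achieved_spec` fields).

Under the dual rule, values strictly below the lower cutoff are negative,
strictly above the upper cutoff positive, and everything else — including
values exactly equal to either cutoff — intermediate; the published
notation ("<lower", ">upper") is read as strict inequalities and the
boundary convention is flagged here because it is not stated explicitly.
If a derived pair inverts (lower > upper, possible for a near-separable
marker in a small derivation sample), the set is flagged with a warning
and classification collapses the pair to its midpoint (an empty gray
zone).

# Metrics and comparisons

Intermediate subjects are counted in the intermediate fraction and
excluded from accuracy, sensitivity, specificity, PPV and NPV, which come
from the 2×2 table of the remaining subjects. The exclusion is applied to
all five rates for coherence (the published analysis reports only
accuracy/PPV/NPV/AUC under the dual rule). Undefined metrics (empty
margins) propagate as `NA`, never 0 or 1, so bootstrap CIs are not
silently biased; resamples with undefined metrics are redrawn, and a
metric undefined on the full data gets no CI. AUC is the rank statistic
(ties at half weight), identical to trapezoidal ROC integration. Reported
prevalence is the observed prevalence among classified subjects, with no
standardization.

`delong_test()` computes the AUC difference with the structural-component
(placement) variance — covariance included when the two markers share
subjects — and a two-sided normal p-value. `bootstrap_metric_test()`
implements the published bootstrap hypothesis test; the test names its
p-value rule (proportion of resamples whose absolute null-distributed
statistic reaches the observed difference) but not the null construction,
so the standard recentring ("shift") construction is adopted: each
resample's difference minus the observed difference forms the null
distribution. Paired designs (marker vs marker on the same subjects)
resample subjects jointly; unpaired contrasts (cohorts, care levels,
subgroup levels) resample each group independently — whether the published
unpaired comparisons resample jointly is unstated, and independent
resampling is the interpretation taken. P-values are reported unadjusted,
matching the published analysis; age bands are fixed at <73, 73–80, ≥80
years (a median split at 73 within the under-80s) and configurable.

# Cost model

A triage strategy pays for a plasma test for everyone plus a confirmatory
test (CSF by default) for the intermediate fraction; the comparator pays
for one CSF or PET test per patient. Savings are
$1 - \mathrm{cost}_{\mathrm{strategy}}/\mathrm{cost}_{\mathrm{comparator}}$,
affine in both the intermediate fraction and the plasma cost, with
break-even at $\mathrm{cost}_{\mathrm{plasma}} =
(1-p_{\mathrm{int}})\cdot\mathrm{cost}_{\mathrm{comparator}}$ when the
confirmatory test is the comparator. Costs are strictly inputs;
`default_us_costs()` ships illustrative round US figures (plasma \$250,
CSF \$1,000, amyloid PET \$2,100) for the worked examples, to be replaced
by regional costs. An optional extension also confirms plasma-positive
patients (relevant when a positive result gates treatment), off by
default. There is no discounting and no downstream-care modelling: this is
a test-cost comparison.

# Pipeline

`run_pipeline()` chains the stages: simulate or load cohorts, fit the
reference GMM on all pooled CSF values, freeze per-marker cutoff sets on
the derivation cohort, evaluate every cohort under both rules (the
derivation cohort's own rows are labelled in-sample), run marker,
care-level and subgroup comparisons, and price the triage strategy at the
pooled intermediate fraction. A single global seed spawns a deterministic
sub-stream per stage (`substream_seed()`), so any stage can be reproduced
in isolation and the full report is byte-stable under its seed. Reports
are tidy tibbles, written as CSV plus a JSON manifest; cutoff sets
round-trip through JSON at full decimal precision.

# What the tests do and do not show

The test suite checks the machinery against independent oracles:
exhaustive threshold scans, trapezoidal ROC integration, closed-form
mixture moments, numerically solved equal-posterior points, sign-flip
permutation for the paired DeLong test (compared on the mid-p scale, since
the n = 12 permutation distribution is discrete in steps of 1/36), a
10,000-resample bootstrap SE, null-calibration simulations (1,000
equal-distribution pairs at n = 300 with 500-resample tests), and an
external EM implementation. Study-shape simulations run at the published
cohort sizes (e.g. 100 derivation-evaluation replicates at n = 337);
moment-recovery checks run at n = 50,000. These sizes are the package's
own choices balancing statistical resolution against suite runtime.

Passing tests show that the *machinery* is correct and that the generator
realizes its calibration. They do not show that real plasma p-tau217 data
are log-normal with shared log-variance — real CSF-confirmed cohorts are
more sharply bimodal than this model, which is why the generator's
intermediate fractions (typically around 20% under the dual rule at
AUC 0.95) sit at or slightly above the upper end of the published 12–17%
range. Cohort-level published numbers are not reproducible without the
restricted clinical data, and nothing here claims otherwise.

# Known limitations

* Single two-component univariate GMM only; no ≥3-component or
  multivariate mixtures.
* No assay analytical error, batch effects, or longitudinal trajectories
  in the generator; covariates are independent of class.
* No smoothed/parametric ROC cutoffs and no cost-weighted thresholds
  beyond Youden; no partial AUC.
* The cost model is per-patient and single-currency, without
  health-economic (QALY) structure.
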