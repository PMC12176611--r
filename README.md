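# adtriage

Evaluation machinery for blood-based Alzheimer's disease (AD) biomarkers
used as a triage test: derive single and dual (two-cutoff) thresholds with
a bootstrap procedure, classify patients into negative / intermediate /
positive, estimate the resulting diagnostic performance with bootstrap
confidence intervals, compare markers and subgroups with DeLong and
bootstrap hypothesis tests, and price a blood-test-first triage pathway
against CSF- or PET-only testing.

The package is aimed at biostatisticians and clinical researchers
validating plasma p-tau217 (or similar markers) against a CSF/PET
reference standard, where the workflow is: establish cutoffs in one
derivation cohort, freeze them, and evaluate them out-of-sample in
independent cohorts. Because such clinical datasets are typically shared
only on request, the package also ships a calibrated synthetic-cohort
generator so the entire workflow is runnable and testable end to end.

## Methods at a glance

* **Reference standard.** AD pathology is defined by the CSF Aβ42:p-tau181
  ratio below a cutoff derived by two-component Gaussian mixture modeling:
  EM fits `w₁N(μ₁,σ₁²) + w₂N(μ₂,σ₂²)` and the cutoff is the
  equal-posterior point between the component means. A fixed-cutoff mode
  (11.94, or Aβ42:40 ≤ 0.072) and an amyloid-PET visual-read fallback for
  subjects without CSF are included.
* **Cutoffs.** With positivity defined as `value > c`, the single cutoff
  achieves 90% specificity with maximal sensitivity; the dual pair
  achieves 95% sensitivity (lower) and 95% specificity (upper); a
  Youden-index cutoff (max sens + spec − 1) is available. Each is the mean
  of 2,000 bootstrap replicates with a 2.5/97.5-percentile CI.
* **Triage metrics.** Dual rule: negative if `v < lower`, positive if
  `v > upper`, else intermediate. Intermediates are excluded from
  accuracy, sensitivity, specificity, PPV and NPV and reported as an
  intermediate fraction. AUC is the Mann–Whitney rank statistic
  (= trapezoidal ROC area). All CIs are percentile bootstrap.
* **Comparisons.** ΔAUC via DeLong structural components (paired or
  unpaired); accuracy/PPV/NPV differences via a recentred bootstrap
  hypothesis test: `p = #{|δ*ᵦ − δ̂| ≥ |δ̂|} / B`.
* **Cost model.** Expected per-patient cost of plasma-first triage,
  `c_plasma + p_int · c_confirm`, against a comparator test for everyone;
  savings `= 1 − cost_strategy / cost_comparator`.

## Worked example

Derive cutoffs on a Malmö-calibrated synthetic derivation cohort (n = 337,
AD prevalence 45.4%, pooled plasma p-tau217 0.36 ± 0.33 pg/ml) and
evaluate the dual rule in-sample:

```r
library(adtriage)

co <- generate_cohort(default_cohort_params("Malmö", seed = 1L))
cs <- derive_cutoff_set(co$plasma_ptau217, co$ad_status,
                        marker_name = "plasma_ptau217",
                        derivation_cohort = "Malmö", n_boot = 2000, seed = 1)
cs
#> Cutoff set for plasma_ptau217 (derived in Malmö)
#>   single (>): 0.2976 [0.2615, 0.3333]
#>   lower  (<): 0.2091 [0.1656, 0.2397]
#>   upper  (>): 0.3728 [0.3016, 0.4543]

metric_table(co$plasma_ptau217, co$ad_status, cs, "dual",
             n_boot = 2000, seed = 1)
#> # A tibble: 8 × 5
#>   metric                estimate ci_low ci_high     n
#>   <chr>                    <dbl>  <dbl>   <dbl> <int>
#> 1 accuracy                 0.943  0.913   0.970   247
#> 2 sensitivity              0.95   0.905   0.990   247
#> 3 specificity              0.939  0.897   0.974   247
#> 4 ppv                      0.913  0.859   0.966   247
#> 5 npv                      0.965  0.929   0.993   247
#> 6 intermediate_fraction    0.267  0.223   0.315   337
#> 7 prevalence               0.405 NA      NA       247
#> 8 auc                      0.941  0.918   0.963   337
```

The cutoffs land where a 0.36 ± 0.33 pg/ml marker with AUC ≈ 0.95 puts
them (single ≈ 0.30 pg/ml, gray zone ≈ 0.21–0.37 pg/ml); excluding the
26.7% intermediate subjects lifts accuracy from the single-cutoff level to
94.3% on the remaining 247. The reference-standard cutoff and the triage
economics:

```r
fit_gmm_cutoff(co$csf_ab42_ptau181, seed = 1)
#> Two-component Gaussian mixture cutoff
#>   cutoff: 10.75  (n = 337, converged)
#>   components: mean 6.09 sd 1.531 w 0.413 | mean 33.06 sd 8.761 w 0.587

triage_cost(cost_scenario(250, 1000, 2100, p_intermediate = 0.147))$savings_fraction
#> [1] 0.603
```

With a \$250 plasma test, \$1,000 CSF panel and 14.7% of patients needing
confirmatory CSF, triage costs \$397 per patient — a 60.3% saving over CSF
for everyone.

The full five-cohort workflow (simulate, reference labels, freeze cutoffs
on the derivation cohort, evaluate out-of-sample, subgroup and marker
comparisons, cost table) is one call:

```r
report <- run_pipeline(run_config(mode = "simulate", seed = 1L))
```

A thin CLI over the same functions is in
`inst/scripts/adtriage-cli.R` (subcommands `simulate`, `derive-cutoffs`,
`evaluate`, `compare`, `cost`, `run-all`).

## Scope

The package evaluates triage rules; it does not model assay chemistry,
PET acquisition, participant recruitment, or health-economic outcomes
beyond test costs. See the methods vignette
(`vignettes/triage-evaluation-methods.Rmd`) for the model, its
assumptions, and known limitations.
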