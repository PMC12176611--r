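test_that("built-in cohort parameters match the published characteristics", {
  p <- default_cohort_params("Malmö")
  expect_equal(p$n, 337L)
  expect_equal(p$prevalence, 0.454)
  pc <- default_cohort_params("Primary care (Sweden)")
  expect_equal(pc$n, 548L)
  expect_equal(pc$prevalence, 0.445)
  expect_equal(pc$care_level, "primary")
  # implied pooled plasma p-tau217 mean within the published 0.36 (0.33)
  mm <- cohort_moments(p)
  ptau <- mm[mm$marker == "plasma_ptau217", ]
  expect_lt(abs(ptau$mean - 0.36), 0.05)
  expect_error(default_cohort_params("Lund"), "Malmö")
})

test_that("generation is deterministic under the seed and varies across seeds", {
  p <- default_cohort_params("Gothenburg", seed = 7L)
  a <- generate_cohort(p)
  b <- generate_cohort(p)
  expect_identical(a, b)
  c3 <- generate_cohort(p, seed = 8L)
  expect_false(identical(a$plasma_ptau217, c3$plasma_ptau217))
})

test_that("class labels are drawn at the configured prevalence", {
  p <- cohort_params("test", "secondary", n = 20000, prevalence = 0.455,
                     markers = list(m = list(mean = 1, sd = 0.5,
                                             auc = 0.9)),
                     seed = 3L)
  co <- generate_cohort(p)
  expect_equal(nrow(co), 20000)
  expect_lt(abs(mean(co$ad_status == "positive") - 0.455), 0.015)
})

test_that("identical class distributions give a no-signal marker", {
  p <- cohort_params("null", "secondary", n = 20000, prevalence = 0.5,
                     markers = list(m = list(meanlog = c(0, 0),
                                             sdlog = c(0.5, 0.5))),
                     seed = 5L)
  co <- generate_cohort(p)
  expect_lt(abs(auc_rank(co$m, co$ad_status) - 0.5), 0.02)
})

test_that("empirical moments recover the analytic mixture moments", {
  p <- default_cohort_params("Malmö", seed = 11L)
  p$n <- 50000L
  co <- generate_cohort(p)
  mm <- cohort_moments(p)
  for (i in seq_len(nrow(mm))) {
    x <- co[[mm$marker[i]]]
    expect_lt(abs(mean(x) - mm$mean[i]) / mm$mean[i], 0.05,
              label = paste("mean of", mm$marker[i]))
    expect_lt(abs(sd(x) - mm$sd[i]) / mm$sd[i], 0.05,
              label = paste("sd of", mm$marker[i]))
  }
})

test_that("an AUC target is realized empirically (signal control)", {
  p <- cohort_params("auc", "secondary", n = 50000, prevalence = 0.45,
                     markers = list(m = list(mean = 1, sd = 0.8,
                                             auc = 0.90)),
                     seed = 13L)
  co <- generate_cohort(p)
  expect_lt(abs(auc_rank(co$m, co$ad_status) - 0.90), 0.01)
})

test_that("a CKD multiplier above 1 elevates the marker within each class", {
  p <- cohort_params(
    "ckd", "secondary", n = 40000, prevalence = 0.5,
    markers = list(m = list(mean = 1, sd = 0.6, auc = 0.95)),
    covariate_effects = list(m = list(ckd = c(1.4, 1.4))),
    covariate_prevalences = list(ckd = 0.3), seed = 17L)
  co <- generate_cohort(p)
  for (cls in c("positive", "negative")) {
    sub <- co[co$ad_status == cls, ]
    expect_gt(mean(sub$m[sub$ckd]), mean(sub$m[!sub$ckd]))
  }
})

test_that("generated records satisfy the structural invariants", {
  co <- generate_cohort(default_cohort_params("Primary care (Sweden)",
                                              seed = 23L))
  markers <- c("plasma_ptau217", "plasma_ab42", "ms_ptau217",
               "ms_np_ptau217", "csf_ab42_ptau181", "csf_ab42_40")
  for (mk in markers) expect_true(all(co[[mk]] > 0, na.rm = TRUE))
  pct <- co$ms_ptau217 / co$ms_np_ptau217 * 100
  expect_true(all(pct > 0 & pct < 100))
  expect_true(all(co$age >= 40 & co$age <= 100))
  expect_true(all(co$age_band %in% c("<73", "73-80", ">=80")))
  # PET read exists exactly where CSF is missing; count matches the config
  expect_identical(is.na(co$csf_ab42_ptau181), !is.na(co$pet_visual_read))
  expect_equal(sum(is.na(co$csf_ab42_ptau181)), 87)
  expect_true(all(co$ad_status %in% c("positive", "negative")))
})

test_that("invalid parameters are rejected", {
  mk <- list(m = list(mean = 1, sd = 0.5, auc = 0.9))
  expect_error(cohort_params("x", "secondary", n = 0, prevalence = 0.5,
                             markers = mk), "positive integer")
  expect_error(cohort_params("x", "secondary", n = 10, prevalence = 1.5,
                             markers = mk), "prevalence")
  expect_error(
    cohort_params("x", "secondary", n = 10, prevalence = 0.5,
                  markers = list(m = list(meanlog = c(0, 1),
                                          sdlog = c(0, 0.5)))),
    "non-positive")
  expect_error(
    cohort_params("x", "secondary", n = 10, prevalence = 0.5, markers = mk,
                  covariate_prevalences = list(stage = c(0.5, 0.2, 0.2))),
    "sum to 1")
})
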