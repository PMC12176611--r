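test_that("triage classification follows the boundary conventions", {
  pred <- classify_triage(c(0.50, 0.27, 0.22, 0.34, 0.10, NA),
                          c(0.22, 0.34), mode = "dual")
  expect_equal(as.character(pred),
               c("positive", "intermediate", "intermediate", "intermediate",
                 "negative", NA))
  single <- classify_triage(c(0.27, 0.271, NA), 0.27, mode = "single")
  expect_equal(as.character(single), c("negative", "positive", NA))
  expect_false(any(single == "intermediate", na.rm = TRUE))
  expect_error(classify_triage(1, c(2, 1), "dual"), "lower")
})

test_that("dual classification reduces to single when the cutoffs coincide", {
  set.seed(41)
  v <- rnorm(500) # continuous: no mass on the boundary
  cc <- 0.3
  dual <- classify_triage(v, c(cc, cc), "dual")
  single <- classify_triage(v, cc, "single")
  expect_equal(as.character(dual), as.character(single))
})

test_that("confusion metrics implement the intermediate-exclusion rule", {
  pred <- factor(rep(c("positive", "positive", "negative", "negative"),
                     c(90, 10, 20, 80)),
                 levels = c("negative", "intermediate", "positive"))
  truth <- rep(c(1, 0, 1, 0), c(90, 10, 20, 80))
  m <- confusion_metrics(pred, truth)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$ppv, 0.90)
  expect_equal(m$npv, 0.80)
  expect_equal(m$sensitivity, 90 / 110)
  expect_equal(m$specificity, 80 / 90)
  expect_equal(m$intermediate_fraction, 0)

  # all-correct case
  pred2 <- factor(rep(c("positive", "negative"), c(5, 5)),
                  levels = levels(pred))
  m2 <- confusion_metrics(pred2, rep(c(1, 0), c(5, 5)))
  expect_equal(m2$accuracy, 1)
  expect_equal(m2$ppv, 1)
  expect_equal(m2$npv, 1)
})

test_that("the Bayes identity links PPV to sens/spec/prevalence", {
  co <- generate_cohort(default_cohort_params("Barcelona", seed = 19L))
  pred <- classify_triage(co$plasma_ptau217, c(0.22, 0.34), "dual")
  m <- confusion_metrics(pred, co$ad_status)
  pi <- m$prevalence
  expect_equal(m$ppv,
               m$sensitivity * pi /
                 (m$sensitivity * pi + (1 - m$specificity) * (1 - pi)),
               tolerance = 1e-12)
})

test_that("empty margins yield undefined metrics, not zeros", {
  pred <- factor(rep("negative", 10),
                 levels = c("negative", "intermediate", "positive"))
  m <- confusion_metrics(pred, rep(c(1, 0), 5))
  expect_true(is.na(m$ppv))
  expect_false(is.na(m$npv))
  expect_equal(m$accuracy, 0.5)
})

test_that("rank AUC matches hand-counted pairs and is tie-aware", {
  expect_equal(auc_rank(c(3, 1, 2, 0), c(1, 1, 0, 0)), 0.75)
  d <- sep_example()
  expect_equal(auc_rank(d$values, d$labels), 0.955)
  # identical value sets in both classes: all-ties, exactly 0.5
  expect_equal(auc_rank(c(1:5, 1:5), rep(c(0, 1), each = 5)), 0.5)
  expect_error(auc_rank(1:4, rep(1, 4)), "both")
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(71)
  for (i in 1:10) {
    d <- random_small_data(80)
    ours <- auc_rank(d$values, d$labels)
    ref <- as.numeric(pROC::auc(pROC::roc(d$labels, d$values,
                                          quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("bootstrap CIs are deterministic, degenerate-safe and bracket", {
  pred <- factor(rep(c("positive", "negative"), c(30, 30)),
                 levels = c("negative", "intermediate", "positive"))
  truth <- rep(c(1, 0), c(30, 30))
  # perfectly classified data: every resample has accuracy 1
  b <- bootstrap_ci("accuracy", truth, pred = pred, n_boot = 100, seed = 1)
  expect_equal(b$ci_low, 1)
  expect_equal(b$ci_high, 1)
  co <- generate_cohort(default_cohort_params("Malmö", seed = 29L))
  pred2 <- classify_triage(co$plasma_ptau217, c(0.22, 0.34), "dual")
  b1 <- bootstrap_ci("accuracy", co$ad_status, pred = pred2, n_boot = 200,
                     seed = 5)
  b2 <- bootstrap_ci("accuracy", co$ad_status, pred = pred2, n_boot = 200,
                     seed = 5)
  expect_identical(b1, b2)
  for (s in 1:10) {
    cos <- generate_cohort(default_cohort_params("Gothenburg"), seed = s)
    preds <- classify_triage(cos$plasma_ptau217, c(0.22, 0.34), "dual")
    est <- confusion_metrics(preds, cos$ad_status)$accuracy
    bs <- bootstrap_ci("accuracy", cos$ad_status, pred = preds,
                       n_boot = 200, seed = s)
    expect_lte(bs$ci_low, est)
    expect_gte(bs$ci_high, est)
  }
})

test_that("exclusion consistency: accuracy uses exactly the non-intermediates", {
  co <- generate_cohort(default_cohort_params("Brescia", seed = 37L))
  pred <- classify_triage(co$plasma_ptau217, c(0.22, 0.34), "dual")
  cm <- confusion_metrics(pred, co$ad_status)
  cnt <- cm$counts
  expect_equal(sum(cnt[c("TP", "FP", "FN", "TN", "n_intermediate")]),
               cnt[["n_total"]])
  expect_equal(cm$accuracy,
               (cnt[["TP"]] + cnt[["TN"]]) /
                 (cnt[["n_total"]] - cnt[["n_intermediate"]]))
})

test_that("metric_table assembles estimates, CIs and counts coherently", {
  co <- generate_cohort(default_cohort_params("Malmö", seed = 43L))
  tb <- metric_table(co$plasma_ptau217, co$ad_status, c(0.22, 0.34),
                     "dual", n_boot = 100, seed = 3)
  expect_setequal(tb$metric,
                  c("accuracy", "sensitivity", "specificity", "ppv", "npv",
                    "intermediate_fraction", "prevalence", "auc"))
  perf <- tb[tb$metric != "prevalence", ]
  expect_true(all(perf$ci_low <= perf$estimate + 1e-12))
  expect_true(all(perf$ci_high >= perf$estimate - 1e-12))
  cnt <- attr(tb, "counts")
  expect_equal(tb$n[tb$metric == "accuracy"],
               sum(cnt[c("TP", "FP", "FN", "TN")]))
})
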