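test_that("DeLong self-comparison and rank invariance", {
  co <- generate_cohort(default_cohort_params("Malmö", seed = 3L))
  v <- co$plasma_ptau217
  r <- delong_test(v, v, co$ad_status, paired = TRUE)
  expect_equal(r$delta, 0)
  expect_equal(r$p_value, 1)
  # a strictly monotone transform leaves the AUC untouched
  r2 <- delong_test(v, log(v) + 100, co$ad_status, paired = TRUE)
  expect_equal(r2$delta, 0)
  expect_equal(r2$p_value, 1)
})

test_that("paired and unpaired DeLong match pROC::roc.test", {
  skip_if_not_installed("pROC")
  co <- generate_cohort(default_cohort_params("Gothenburg", seed = 7L))
  truth <- co$ad_status == "positive"
  va <- co$plasma_ptau217
  vb <- co$ms_ptau217
  ours <- delong_test(va, vb, truth, paired = TRUE)
  ra <- pROC::roc(truth, va, quiet = TRUE, direction = "<")
  rb <- pROC::roc(truth, vb, quiet = TRUE, direction = "<")
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  expect_equal(ours$delta,
               as.numeric(ref$estimate[1] - ref$estimate[2]),
               tolerance = 1e-12)

  co2 <- generate_cohort(default_cohort_params("Brescia", seed = 8L))
  truth2 <- co2$ad_status == "positive"
  ours_u <- delong_test(va, co2$plasma_ptau217, truth,
                        truth_b = truth2, paired = FALSE)
  ref_u <- pROC::roc.test(
    ra, pROC::roc(truth2, co2$plasma_ptau217, quiet = TRUE,
                  direction = "<"),
    method = "delong", paired = FALSE)
  # same statistic; pROC converts it with a Welch t rather than a normal,
  # so the p-values agree only approximately
  expect_equal(ours_u$delta / ours_u$se, as.numeric(ref_u$statistic),
               tolerance = 1e-9)
  expect_equal(ours_u$p_value, ref_u$p.value, tolerance = 0.01)
})

test_that("swapping the groups negates delta and preserves p", {
  co <- generate_cohort(default_cohort_params("Malmö", seed = 11L))
  truth <- co$ad_status
  ab <- delong_test(co$plasma_ptau217, co$ms_ptau217, truth, paired = TRUE)
  ba <- delong_test(co$ms_ptau217, co$plasma_ptau217, truth, paired = TRUE)
  expect_equal(ab$delta, -ba$delta)
  expect_equal(ab$p_value, ba$p_value)
  pr_a <- classify_triage(co$plasma_ptau217, 0.27, "single")
  pr_b <- classify_triage(co$ms_ptau217, 2.27, "single")
  t_ab <- bootstrap_metric_test("accuracy", truth_a = truth, pred_a = pr_a,
                                pred_b = pr_b, paired = TRUE,
                                n_boot = 300, seed = 5)
  t_ba <- bootstrap_metric_test("accuracy", truth_a = truth, pred_a = pr_b,
                                pred_b = pr_a, paired = TRUE,
                                n_boot = 300, seed = 5)
  expect_equal(t_ab$delta, -t_ba$delta)
  expect_equal(t_ab$p_value, t_ba$p_value)
})

test_that("identical groups give p = 1 exactly and same-seed reproducibility", {
  co <- generate_cohort(default_cohort_params("Malmö", seed = 13L))
  pred <- classify_triage(co$plasma_ptau217, 0.27, "single")
  r <- bootstrap_metric_test("accuracy", truth_a = co$ad_status,
                             pred_a = pred, pred_b = pred, paired = TRUE,
                             n_boot = 200, seed = 2)
  expect_equal(r$delta, 0)
  expect_equal(r$p_value, 1)
  r2 <- bootstrap_metric_test("accuracy", truth_a = co$ad_status,
                              truth_b = co$ad_status, pred_a = pred,
                              pred_b = pred, paired = FALSE, n_boot = 200,
                              seed = 9)
  r3 <- bootstrap_metric_test("accuracy", truth_a = co$ad_status,
                              truth_b = co$ad_status, pred_a = pred,
                              pred_b = pred, paired = FALSE, n_boot = 200,
                              seed = 9)
  expect_identical(r2$p_value, r3$p_value)
})

test_that("the bootstrap test detects a large real accuracy difference", {
  # group A ~90% accurate, group B ~70% accurate, n = 400 per group
  for (s in 1:5) {
    set.seed(s)
    truth <- rep(c(1, 0), each = 200)
    correct_a <- rbinom(400, 1, 0.90) == 1
    correct_b <- rbinom(400, 1, 0.70) == 1
    mk_pred <- function(correct) {
      factor(ifelse(truth == 1,
                    ifelse(correct, "positive", "negative"),
                    ifelse(correct, "negative", "positive")),
             levels = c("negative", "intermediate", "positive"))
    }
    r <- bootstrap_metric_test("accuracy", truth_a = truth,
                               truth_b = truth, pred_a = mk_pred(correct_a),
                               pred_b = mk_pred(correct_b), paired = FALSE,
                               n_boot = 500, seed = s)
    expect_lt(r$p_value, 0.05)
    expect_gt(r$delta, 0)
  }
})

test_that("subgroup analysis with one level reproduces the overall table", {
  co <- generate_cohort(default_cohort_params("Brescia", seed = 17L))
  co$one <- "all"
  co$cohort_name <- "all" # single-level factor
  sg <- subgroup_analysis(co, "plasma_ptau217", c(0.22, 0.34),
                          "cohort_name", "dual", truth_col = "ad_status",
                          n_boot = 50, seed = 3)
  overall <- metric_table(co$plasma_ptau217, co$ad_status, c(0.22, 0.34),
                          "dual", n_boot = 50,
                          seed = substream_seed(3, "level/all"))
  expect_equal(sg$metrics$estimate, overall$estimate)
  expect_equal(nrow(sg$comparisons), 0)
})

test_that("levels with a single truth class are reported but not compared", {
  co <- generate_cohort(default_cohort_params("Malmö", seed = 19L))
  co$stage[co$stage == "SCD"] <- "MCI"
  co$ad_status[co$stage == "dementia"] <- "positive" # degenerate level
  sg <- subgroup_analysis(co, "plasma_ptau217", c(0.22, 0.34), "stage",
                          "dual", truth_col = "ad_status", n_boot = 50,
                          seed = 7)
  expect_true("dementia" %in% sg$metrics$level)
  expect_gt(nrow(sg$skipped), 0)
  expect_false(any(sg$comparisons$level_b == "dementia" |
                     sg$comparisons$level_a == "dementia"))
})
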