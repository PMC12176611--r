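test_that("worked separable example yields the expected operating points", {
  d <- sep_example()
  at_spec <- empirical_cutoff(d$values, d$labels, "at_specificity", 0.90)
  expect_equal(at_spec$cutoff, 9.5)
  expect_equal(at_spec$achieved_spec, 0.90)
  expect_equal(at_spec$achieved_sens, 0.80)
  at_sens <- empirical_cutoff(d$values, d$labels, "at_sensitivity", 0.95)
  expect_equal(at_sens$cutoff, 7.5)
  expect_equal(at_sens$achieved_sens, 1.00)
  expect_equal(at_sens$achieved_spec, 0.70)
})

test_that("perfectly separated classes give a perfect cutoff", {
  values <- c(rnorm(20, 0, 0.1), rnorm(15, 10, 0.1))
  labels <- rep(c(0, 1), c(20, 15))
  for (m in c("at_specificity", "at_sensitivity", "youden")) {
    r <- empirical_cutoff(values, labels, m, 0.95)
    expect_gt(r$cutoff, max(values[labels == 0]))
    expect_lt(r$cutoff, min(values[labels == 1]))
    expect_equal(r$achieved_sens, 1)
    expect_equal(r$achieved_spec, 1)
  }
})

test_that("the returned threshold always honors its target (guarantee)", {
  set.seed(201)
  for (rep in 1:30) {
    d <- random_small_data()
    for (tl in c(0.8, 0.9, 0.95)) {
      rs <- empirical_cutoff(d$values, d$labels, "at_specificity", tl)
      expect_gte(rs$achieved_spec, tl)
      rn <- empirical_cutoff(d$values, d$labels, "at_sensitivity", tl)
      expect_gte(rn$achieved_sens, tl)
    }
  }
})

test_that("youden ties break toward the higher-specificity threshold", {
  # 1.5 and 3.5 share the maximal Youden index (0.5); the
  # higher-specificity threshold 3.5 wins
  values <- c(1, 3, 2, 4)
  labels <- c(0, 0, 1, 1)
  r <- empirical_cutoff(values, labels, "youden")
  expect_equal(r$cutoff, 3.5)
  expect_equal(r$achieved_spec, 1)
})

test_that("single-class or constant input is rejected", {
  expect_error(empirical_cutoff(1:5, rep(1, 5), "youden"), "both")
  expect_error(empirical_cutoff(rep(2, 6), rep(c(0, 1), 3), "youden"),
               "identical")
})

test_that("degenerate two-point data gives the exact midpoint, zero-width CI", {
  values <- c(rep(1, 8), rep(3, 9))
  labels <- rep(c(0, 1), c(8, 9))
  b <- bootstrap_cutoff(values, labels, "at_specificity", 0.90,
                        n_boot = 200, seed = 4)
  expect_equal(b$cutoff, 2.0)
  expect_equal(b$ci_low, 2.0)
  expect_equal(b$ci_high, 2.0)
  expect_equal(b$achieved_sens, 1)
  expect_equal(b$achieved_spec, 1)
})

test_that("bootstrap cutoffs are reproducible under the seed", {
  set.seed(301)
  d <- random_small_data()
  b1 <- bootstrap_cutoff(d$values, d$labels, "at_specificity", 0.90,
                         n_boot = 100, seed = 9)
  b2 <- bootstrap_cutoff(d$values, d$labels, "at_specificity", 0.90,
                         n_boot = 100, seed = 9)
  expect_identical(b1, b2)
})

test_that("the bootstrap CI narrows as the derivation sample grows", {
  widths <- sapply(1:20, function(s) {
    co_small <- generate_cohort(default_cohort_params("Malmö"), seed = s)
    p_big <- default_cohort_params("Malmö"); p_big$n <- 1000L
    co_big <- generate_cohort(p_big, seed = s + 1000L)
    w <- function(co, n) {
      idx <- seq_len(n)
      b <- bootstrap_cutoff(co$plasma_ptau217[idx], co$ad_status[idx],
                            "at_specificity", 0.90, n_boot = 200, seed = s)
      b$ci_high - b$ci_low
    }
    c(small = w(co_small, 100), big = w(co_big, 1000))
  })
  expect_lt(mean(widths["big", ]), mean(widths["small", ]))
})

test_that("a derived cutoff set is ordered and round-trips through JSON", {
  co <- generate_cohort(default_cohort_params("Malmö", seed = 5L))
  cs <- derive_cutoff_set(co$plasma_ptau217, co$ad_status,
                          marker_name = "plasma_ptau217",
                          derivation_cohort = "Malmö", n_boot = 200,
                          seed = 2)
  expect_lte(cs$lower$cutoff, cs$upper$cutoff)
  expect_lte(cs$single$ci_low, cs$single$cutoff)
  expect_lte(cs$single$cutoff, cs$single$ci_high)
  path <- withr::local_tempfile(fileext = ".json")
  write_cutoff_set(cs, path)
  cs2 <- read_cutoff_set(path)
  expect_identical(cs2$single$cutoff, cs$single$cutoff)
  expect_identical(cs2$lower$ci_low, cs$lower$ci_low)
  expect_identical(cs2$marker_name, "plasma_ptau217")
})
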