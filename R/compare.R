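# DeLong structural components via midranks: V10 placements for positives,
# V01 for negatives; mean(V10) = mean(V01) = AUC
delong_placements <- function(values, pos) {
  r_all <- rank(values)
  r_pos <- rank(values[pos])
  r_neg <- rank(values[!pos])
  n_pos <- sum(pos); n_neg <- sum(!pos)
  V10 <- (r_all[pos] - r_pos) / n_neg
  V01 <- 1 - (r_all[!pos] - r_neg) / n_pos
  list(V10 = V10, V01 = V01, auc = mean(V10), n_pos = n_pos, n_neg = n_neg)
}

comparison_result <- function(metric_name, delta, p_value, method, paired,
                              estimate_a, estimate_b, n_boot = NA_integer_,
                              seed = NA_integer_, se = NA_real_,
                              note = NA_character_) {
  structure(
    list(metric_name = metric_name, delta = delta, p_value = p_value,
         method = method, paired = paired, estimate_a = estimate_a,
         estimate_b = estimate_b, n_boot = n_boot, seed = seed, se = se,
         note = note),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s comparison (%s, %s): delta = %.4g, p = %.4g\n",
              x$metric_name, x$method,
              if (isTRUE(x$paired)) "paired" else "unpaired",
              x$delta, x$p_value))
  cat(sprintf("  estimates: %.4g vs %.4g\n", x$estimate_a, x$estimate_b))
  invisible(x)
}

#' DeLong test for a difference between two AUCs
#'
#' Compares two empirical AUCs using DeLong's structural-component variance
#' estimate; the paired form (two markers on the same subjects) includes
#' the covariance term, the unpaired form (two independent groups, each
#' with its own reference labels) sums the two variances. The p-value is
#' two-sided normal.
#'
#' @param values_a,values_b Marker values for the two sides.
#' @param truth Reference labels for side a (and for side b when paired).
#' @param truth_b Reference labels for side b (unpaired only).
#' @param paired `TRUE` when both markers are measured on the same subjects.
#' @return A `comparison_result` with `delta` (AUC_a - AUC_b), `p_value`,
#'   `se` and the two AUC estimates.
#' @export
delong_test <- function(values_a, values_b, truth, truth_b = NULL,
                        paired = TRUE) {
  pos_a <- as_positive(truth)
  if (paired) {
    if (!is.null(truth_b)) {
      stop("paired comparison uses a single shared truth", call. = FALSE)
    }
    keep <- !is.na(values_a) & !is.na(values_b) & !is.na(pos_a)
    va <- values_a[keep]; vb <- values_b[keep]; pos <- pos_a[keep]
    assert_two_classes(pos, "truth")
    pa <- delong_placements(va, pos)
    pb <- delong_placements(vb, pos)
    s10 <- stats::cov(cbind(pa$V10, pb$V10))
    s01 <- stats::cov(cbind(pa$V01, pb$V01))
    v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / pa$n_pos +
      (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / pa$n_neg
    delta <- pa$auc - pb$auc
  } else {
    pos_b <- as_positive(truth_b %||% truth)
    ka <- !is.na(values_a) & !is.na(pos_a)
    kb <- !is.na(values_b) & !is.na(pos_b)
    assert_two_classes(pos_a[ka], "truth (group a)")
    assert_two_classes(pos_b[kb], "truth (group b)")
    pa <- delong_placements(values_a[ka], pos_a[ka])
    pb <- delong_placements(values_b[kb], pos_b[kb])
    v <- var(pa$V10) / pa$n_pos + var(pa$V01) / pa$n_neg +
      var(pb$V10) / pb$n_pos + var(pb$V01) / pb$n_neg
    delta <- pa$auc - pb$auc
  }
  p <- if (abs(delta) < 1e-15) 1 else 2 * pnorm(-abs(delta) / sqrt(v))
  comparison_result("auc", delta, p,
                    if (paired) "delong_paired" else "delong_unpaired",
                    paired, pa$auc, pb$auc, se = sqrt(v))
}

#' Bootstrap hypothesis test for a difference in a performance metric
#'
#' Tests whether a metric (accuracy, PPV, NPV, sensitivity, specificity,
#' intermediate fraction, or AUC) differs between two classifications. A
#' null distribution is built by recentring the bootstrap differences at
#' zero (each resample's difference minus the observed difference); the
#' two-sided p-value is the proportion of resamples whose absolute
#' null-distributed statistic is at least the absolute observed difference.
#' Paired mode resamples subjects jointly; unpaired mode resamples the two
#' groups independently. Resamples where the metric is undefined on either
#' side are redrawn (bounded).
#'
#' @param metric Metric name; `"auc"` uses `values_*`, the others use the
#'   tri-level predictions `pred_*`.
#' @param truth_a,truth_b Reference labels (omit `truth_b` when paired).
#' @param pred_a,pred_b Tri-level predictions for count-based metrics.
#' @param values_a,values_b Marker values (AUC metric).
#' @param paired Jointly resample the same subjects under both sides.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @return A `comparison_result` with the observed `delta` (a - b) and the
#'   bootstrap `p_value`.
#' @export
bootstrap_metric_test <- function(metric, truth_a, truth_b = NULL,
                                  pred_a = NULL, pred_b = NULL,
                                  values_a = NULL, values_b = NULL,
                                  paired = FALSE, n_boot = 2000L,
                                  seed = 1L) {
  stopifnot(n_boot >= 1)
  use_auc <- identical(metric, "auc")
  if (use_auc) {
    stat_one <- function(v, p, idx) {
      pi <- p[idx]
      if (!any(pi) || all(pi)) return(NA_real_)
      r <- rank(v[idx]); np <- sum(pi)
      (sum(r[pi]) - np * (np + 1) / 2) / (np * sum(!pi))
    }
    pos_a <- as_positive(truth_a)
    pos_b <- if (paired) pos_a else as_positive(truth_b %||% truth_a)
    if (paired) {
      keep <- !is.na(values_a) & !is.na(values_b) & !is.na(pos_a)
      da <- list(v = values_a[keep], p = pos_a[keep])
      db <- list(v = values_b[keep], p = pos_b[keep])
    } else {
      ka <- !is.na(values_a) & !is.na(pos_a)
      kb <- !is.na(values_b) & !is.na(pos_b)
      da <- list(v = values_a[ka], p = pos_a[ka])
      db <- list(v = values_b[kb], p = pos_b[kb])
    }
    eval_side <- function(d, idx) stat_one(d$v, d$p, idx)
    n_a <- length(da$v); n_b <- length(db$v)
  } else {
    code_a <- confusion_codes(pred_a, truth_a)
    code_b <- confusion_codes(pred_b, if (paired) truth_a else
                                        (truth_b %||% truth_a))
    if (paired) {
      if (length(code_a) != length(code_b)) {
        stop("paired comparison requires the same subjects on both sides",
             call. = FALSE)
      }
      keep <- !is.na(code_a) & !is.na(code_b)
      da <- code_a[keep]; db <- code_b[keep]
    } else {
      da <- code_a[!is.na(code_a)]; db <- code_b[!is.na(code_b)]
    }
    eval_side <- function(code, idx) {
      tab <- tabulate(code[idx], 5L)
      metric_from_counts(
        c(TP = tab[1], FP = tab[2], FN = tab[3], TN = tab[4],
          n_intermediate = tab[5], n_missing = 0, n_total = length(idx)),
        metric)
    }
    n_a <- length(da); n_b <- length(db)
  }
  if (paired && n_a != n_b) {
    stop("paired comparison requires aligned subjects", call. = FALSE)
  }
  obs_a <- eval_side(da, seq_len(n_a))
  obs_b <- eval_side(db, seq_len(n_b))
  if (is.na(obs_a) || is.na(obs_b)) {
    stop("metric '", metric, "' is undefined on the observed data",
         call. = FALSE)
  }
  delta <- obs_a - obs_b
  deltas <- withr::with_seed(seed, {
    out <- numeric(n_boot)
    attempts_left <- 100 * n_boot
    for (b in seq_len(n_boot)) {
      repeat {
        attempts_left <- attempts_left - 1
        if (attempts_left < 0) {
          stop("metric '", metric,
               "' undefined in too many bootstrap resamples", call. = FALSE)
        }
        if (paired) {
          idx <- sample.int(n_a, n_a, replace = TRUE)
          sa <- eval_side(da, idx); sb <- eval_side(db, idx)
        } else {
          sa <- eval_side(da, sample.int(n_a, n_a, replace = TRUE))
          sb <- eval_side(db, sample.int(n_b, n_b, replace = TRUE))
        }
        if (!is.na(sa) && !is.na(sb)) break
      }
      out[b] <- sa - sb
    }
    out
  })
  null_stat <- deltas - delta
  p <- mean(abs(null_stat) >= abs(delta))
  comparison_result(metric, delta, p, "bootstrap_test", paired, obs_a,
                    obs_b, n_boot = as.integer(n_boot),
                    seed = as.integer(seed))
}

subgroup_factors <- function() {
  c("age_band", "sex", "ckd", "diabetes", "apoe4", "stage", "care_level",
    "cohort_name")
}

#' Stratified performance and pairwise subgroup comparisons
#'
#' Splits a cohort by a demographic, comorbidity or design factor, computes
#' the full [metric_table()] per level (single and dual modes use the same
#' frozen cutoffs), and compares every pair of levels: accuracy, PPV and
#' NPV via the unpaired [bootstrap_metric_test()], AUC via the unpaired
#' [delong_test()]. P-values are reported unadjusted. Levels with a single
#' truth class keep their (partially defined) metric table but are skipped
#' in comparisons, with the reason recorded.
#'
#' @param cohort Cohort tibble.
#' @param marker Marker column name.
#' @param cutoffs Frozen cutoffs from the derivation cohort.
#' @param factor_name One of `age_band`, `sex`, `ckd`, `diabetes`, `apoe4`,
#'   `stage`, `care_level`, `cohort_name`.
#' @param mode Classification mode passed to [classify_triage()].
#' @param truth_col Column holding the reference labels.
#' @param n_boot Bootstrap resamples for CIs and tests.
#' @param seed Integer seed.
#' @param ci Compute per-level bootstrap CIs.
#' @return A list: `metrics` (tibble: level, metric, estimate, ci_low,
#'   ci_high, n), `comparisons` (tibble: level_a, level_b, metric, delta,
#'   p_value, method), `skipped` (tibble of skipped comparisons + reason).
#' @export
subgroup_analysis <- function(cohort, marker, cutoffs, factor_name,
                              mode = c("single", "dual"),
                              truth_col = "ad_status", n_boot = 2000L,
                              seed = 1L, ci = TRUE) {
  mode <- match.arg(mode)
  if (!factor_name %in% subgroup_factors()) {
    stop("factor_name must be one of: ",
         paste(subgroup_factors(), collapse = ", "), call. = FALSE)
  }
  stopifnot(marker %in% names(cohort), truth_col %in% names(cohort))
  fac <- cohort[[factor_name]]
  levels_order <- if (factor_name == "age_band") {
    intersect(age_band_levels(), unique(fac))
  } else if (factor_name == "stage") {
    intersect(c("SCD", "MCI", "dementia"), unique(fac))
  } else {
    sort(unique(as.character(fac)))
  }
  tables <- list()
  usable <- logical(length(levels_order))
  names(usable) <- levels_order
  for (lv in levels_order) {
    sub <- cohort[as.character(fac) == lv, ]
    pos <- as_positive(sub[[truth_col]])
    usable[lv] <- any(pos, na.rm = TRUE) && any(!pos, na.rm = TRUE)
    if (usable[lv]) {
      tb <- metric_table(sub[[marker]], sub[[truth_col]], cutoffs, mode,
                         n_boot = n_boot,
                         seed = substream_seed(seed, paste0("level/", lv)),
                         ci = ci)
    } else {
      pred <- classify_triage(sub[[marker]], cutoffs, mode)
      cm <- confusion_metrics(pred, sub[[truth_col]])
      tb <- tibble::tibble(
        metric = c("accuracy", "sensitivity", "specificity", "ppv", "npv",
                   "intermediate_fraction", "prevalence"),
        estimate = unname(unlist(cm[c("accuracy", "sensitivity",
                                      "specificity", "ppv", "npv",
                                      "intermediate_fraction",
                                      "prevalence")])),
        ci_low = NA_real_, ci_high = NA_real_, n = NA_integer_)
    }
    tb$level <- lv
    tables[[lv]] <- tb
  }
  metrics_tbl <- dplyr::bind_rows(tables)
  metrics_tbl <- metrics_tbl[, c("level", setdiff(names(metrics_tbl),
                                                  "level"))]

  comparisons <- list()
  skipped <- list()
  if (length(levels_order) >= 2) {
    pairs <- utils::combn(levels_order, 2, simplify = FALSE)
    for (pr in pairs) {
      if (!usable[pr[1]] || !usable[pr[2]]) {
        skipped[[length(skipped) + 1]] <- tibble::tibble(
          level_a = pr[1], level_b = pr[2],
          reason = "single truth class in a level")
        next
      }
      sub_a <- cohort[as.character(fac) == pr[1], ]
      sub_b <- cohort[as.character(fac) == pr[2], ]
      pred_a <- classify_triage(sub_a[[marker]], cutoffs, mode)
      pred_b <- classify_triage(sub_b[[marker]], cutoffs, mode)
      for (m in c("accuracy", "ppv", "npv", "intermediate_fraction")) {
        res <- tryCatch(
          bootstrap_metric_test(
            m, truth_a = sub_a[[truth_col]], truth_b = sub_b[[truth_col]],
            pred_a = pred_a, pred_b = pred_b, paired = FALSE,
            n_boot = n_boot,
            seed = substream_seed(seed, paste(pr[1], pr[2], m, sep = "/"))),
          error = function(e) e)
        if (inherits(res, "error")) {
          skipped[[length(skipped) + 1]] <- tibble::tibble(
            level_a = pr[1], level_b = pr[2], reason = conditionMessage(res))
          next
        }
        comparisons[[length(comparisons) + 1]] <- tibble::tibble(
          level_a = pr[1], level_b = pr[2], metric = m, delta = res$delta,
          p_value = res$p_value, method = res$method)
      }
      dl <- delong_test(sub_a[[marker]], sub_b[[marker]],
                        truth = sub_a[[truth_col]],
                        truth_b = sub_b[[truth_col]], paired = FALSE)
      comparisons[[length(comparisons) + 1]] <- tibble::tibble(
        level_a = pr[1], level_b = pr[2], metric = "auc", delta = dl$delta,
        p_value = dl$p_value, method = dl$method)
    }
  }
  list(
    metrics = metrics_tbl,
    comparisons = if (length(comparisons)) dplyr::bind_rows(comparisons)
                  else tibble::tibble(level_a = character(),
                                      level_b = character(),
                                      metric = character(),
                                      delta = numeric(),
                                      p_value = numeric(),
                                      method = character()),
    skipped = if (length(skipped)) dplyr::bind_rows(skipped)
              else tibble::tibble(level_a = character(),
                                  level_b = character(),
                                  reason = character())
  )
}
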