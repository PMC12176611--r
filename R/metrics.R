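tri_levels <- function() c("negative", "intermediate", "positive")

#' Classify marker values under a single- or two-cutoff rule
#'
#' Under the single-cutoff rule a subject is positive when the value is
#' strictly greater than the cutoff, otherwise negative. Under the dual
#' (triage) rule a subject is negative below the lower cutoff (strict `<`),
#' positive above the upper cutoff (strict `>`), and intermediate otherwise
#' — values equal to either cutoff fall in the intermediate zone.
#'
#' @param values Numeric marker values; `NA` values yield `NA` labels
#'   (excluded-but-counted downstream, never silently dropped).
#' @param cutoffs A [derive_cutoff_set()] result, or a single numeric
#'   cutoff (single mode), or `c(lower, upper)` (dual mode).
#' @param mode `"single"` or `"dual"`.
#' @return Factor with levels `negative`, `intermediate`, `positive`.
#' @export
#' @examples
#' classify_triage(c(0.1, 0.27, 0.5), c(0.22, 0.34), mode = "dual")
classify_triage <- function(values, cutoffs, mode = c("single", "dual")) {
  mode <- match.arg(mode)
  if (inherits(cutoffs, "cutoff_set")) {
    cuts <- if (mode == "single") cutoffs$single$cutoff
            else c(cutoffs$lower$cutoff, cutoffs$upper$cutoff)
    if (mode == "dual" && cuts[1] > cuts[2]) {
      # degenerate derivation (near-separable marker): the zone is empty,
      # so both cutoffs collapse to their midpoint
      cuts <- rep(mean(cuts), 2L)
    }
  } else {
    cuts <- as.numeric(cutoffs)
  }
  if (mode == "single") {
    stopifnot(length(cuts) == 1)
    lab <- ifelse(values > cuts, "positive", "negative")
  } else {
    stopifnot(length(cuts) == 2)
    if (cuts[1] > cuts[2]) stop("lower cutoff exceeds upper cutoff",
                                call. = FALSE)
    lab <- ifelse(values < cuts[1], "negative",
                  ifelse(values > cuts[2], "positive", "intermediate"))
  }
  factor(lab, levels = tri_levels())
}

# per-subject confusion codes: 1 TP, 2 FP, 3 FN, 4 TN, 5 intermediate;
# NA for missing prediction or truth
confusion_codes <- function(pred, truth) {
  pos <- as_positive(truth)
  p <- as.character(pred)
  code <- rep(NA_integer_, length(p))
  code[p == "positive" & pos] <- 1L
  code[p == "positive" & !pos] <- 2L
  code[p == "negative" & pos] <- 3L
  code[p == "negative" & !pos] <- 4L
  code[p == "intermediate"] <- 5L
  code
}

#' Confusion counts under the intermediate-exclusion rule
#'
#' @param pred Tri-level predictions from [classify_triage()].
#' @param truth Reference-standard labels.
#' @return Named integer vector: `TP`, `FP`, `FN`, `TN`, `n_intermediate`,
#'   `n_missing`, `n_total`.
#' @export
confusion_counts <- function(pred, truth) {
  code <- confusion_codes(pred, truth)
  tab <- tabulate(code, 5L)
  c(TP = tab[1], FP = tab[2], FN = tab[3], TN = tab[4],
    n_intermediate = tab[5], n_missing = sum(is.na(code)),
    n_total = length(code))
}

metric_from_counts <- function(counts, metric) {
  TP <- counts[["TP"]]; FP <- counts[["FP"]]
  FN <- counts[["FN"]]; TN <- counts[["TN"]]
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  switch(metric,
         accuracy = ratio(TP + TN, TP + FP + FN + TN),
         sensitivity = ratio(TP, TP + FN),
         specificity = ratio(TN, TN + FP),
         ppv = ratio(TP, TP + FP),
         npv = ratio(TN, TN + FN),
         intermediate_fraction = ratio(counts[["n_intermediate"]],
                                       counts[["n_total"]] -
                                         counts[["n_missing"]]),
         prevalence = ratio(TP + FN, TP + FP + FN + TN),
         stop("unknown metric '", metric, "'", call. = FALSE))
}

#' Point-estimate performance metrics of a tri-level classification
#'
#' Subjects with an intermediate result are counted in
#' `intermediate_fraction` but excluded from accuracy, sensitivity,
#' specificity, PPV and NPV, which are computed from the 2x2 table of the
#' remaining subjects. Metrics with an empty margin are reported as `NA`
#' (undefined), never as 0.
#'
#' @inheritParams confusion_counts
#' @return A list: the named metrics, `counts`, and `prevalence` (among
#'   non-intermediate classified subjects).
#' @export
confusion_metrics <- function(pred, truth) {
  counts <- confusion_counts(pred, truth)
  metrics <- c("accuracy", "sensitivity", "specificity", "ppv", "npv",
               "intermediate_fraction", "prevalence")
  out <- lapply(setNames(metrics, metrics), metric_from_counts,
                counts = counts)
  out$counts <- counts
  out
}

#' Rank-based AUC (Mann-Whitney convention)
#'
#' Concordant pairs plus half-weight for ties, over all positive x negative
#' pairs; identical to the trapezoidal area under the empirical ROC curve.
#'
#' @param values Numeric marker values.
#' @param truth Reference-standard labels; both classes must be present.
#' @return The AUC in `[0, 1]`.
#' @export
#' @examples
#' auc_rank(c(3, 1, 2, 0), c(1, 1, 0, 0)) # 0.75
auc_rank <- function(values, truth) {
  pos <- as_positive(truth)
  keep <- !is.na(values) & !is.na(pos)
  values <- values[keep]; pos <- pos[keep]
  assert_two_classes(pos, "AUC input")
  n_pos <- sum(pos); n_neg <- sum(!pos)
  r <- rank(values) # midranks
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Percentile bootstrap confidence interval for a performance metric
#'
#' Resamples subjects with replacement and returns the 2.5th/97.5th
#' percentile interval of the metric across resamples. Resamples where the
#' metric is undefined (an empty margin, or a single class for the AUC)
#' are redrawn, up to a bounded number of attempts.
#'
#' @param metric One of `"accuracy"`, `"sensitivity"`, `"specificity"`,
#'   `"ppv"`, `"npv"`, `"intermediate_fraction"`, `"auc"`.
#' @param truth Reference-standard labels.
#' @param pred Tri-level predictions (count-based metrics).
#' @param values Marker values (required for `"auc"`).
#' @param n_boot Number of resamples.
#' @param seed Integer seed.
#' @param ci_level Confidence level.
#' @return A list: `ci_low`, `ci_high`, `n_redrawn` (resamples redrawn
#'   because the metric was undefined).
#' @export
bootstrap_ci <- function(metric, truth, pred = NULL, values = NULL,
                         n_boot = 2000L, seed = 1L, ci_level = 0.95) {
  stopifnot(n_boot >= 1)
  if (metric == "auc") {
    pos <- as_positive(truth)
    keep <- !is.na(values) & !is.na(pos)
    v <- values[keep]; p <- pos[keep]
    stat <- function(idx) {
      pi <- p[idx]
      if (!any(pi) || all(pi)) return(NA_real_)
      vi <- v[idx]
      r <- rank(vi)
      np <- sum(pi)
      (sum(r[pi]) - np * (np + 1) / 2) / (np * sum(!pi))
    }
    n <- length(v)
  } else {
    code <- confusion_codes(pred, truth)
    code <- code[!is.na(code)]
    stat <- function(idx) {
      tab <- tabulate(code[idx], 5L)
      metric_from_counts(
        c(TP = tab[1], FP = tab[2], FN = tab[3], TN = tab[4],
          n_intermediate = tab[5], n_missing = 0, n_total = length(idx)),
        metric)
    }
    n <- length(code)
  }
  if (n == 0) stop("no usable subjects for metric '", metric, "'",
                   call. = FALSE)
  draws <- withr::with_seed(seed, {
    out <- numeric(n_boot)
    redrawn <- 0L
    attempts_left <- 100 * n_boot
    for (b in seq_len(n_boot)) {
      repeat {
        attempts_left <- attempts_left - 1
        if (attempts_left < 0) {
          stop("metric '", metric,
               "' undefined in too many bootstrap resamples", call. = FALSE)
        }
        s <- stat(sample.int(n, n, replace = TRUE))
        if (!is.na(s)) break
        redrawn <- redrawn + 1L
      }
      out[b] <- s
    }
    list(values = out, redrawn = redrawn)
  })
  ci <- percentile_ci(draws$values, ci_level)
  list(ci_low = ci[["ci_low"]], ci_high = ci[["ci_high"]],
       n_redrawn = draws$redrawn)
}

#' Full metric table for one marker, cohort and classification mode
#'
#' Computes the point estimates of accuracy, sensitivity, specificity, PPV,
#' NPV (intermediates excluded), the intermediate fraction, the prevalence
#' and the cutoff-independent AUC, each with a percentile bootstrap CI.
#'
#' @param values Marker values.
#' @param truth Reference-standard labels.
#' @param cutoffs Cutoffs accepted by [classify_triage()].
#' @param mode `"single"` or `"dual"`.
#' @param n_boot Bootstrap resamples for the CIs.
#' @param seed Integer seed (per-metric sub-streams are derived from it).
#' @param ci Compute bootstrap CIs (set `FALSE` for point estimates only).
#' @return A tibble with columns `metric`, `estimate`, `ci_low`, `ci_high`,
#'   `n` (subjects the metric was computed on); confusion counts are
#'   attached as attribute `"counts"`.
#' @export
metric_table <- function(values, truth, cutoffs, mode = c("single", "dual"),
                         n_boot = 2000L, seed = 1L, ci = TRUE) {
  mode <- match.arg(mode)
  pred <- classify_triage(values, cutoffs, mode)
  pm <- confusion_metrics(pred, truth)
  counts <- pm$counts
  n2x2 <- sum(counts[c("TP", "FP", "FN", "TN")])
  n_classified <- counts[["n_total"]] - counts[["n_missing"]]
  metrics <- c("accuracy", "sensitivity", "specificity", "ppv", "npv",
               "intermediate_fraction", "prevalence", "auc")
  est <- c(unlist(pm[metrics[1:7]]), auc = auc_rank(values, truth))
  ns <- c(rep(n2x2, 5), n_classified, n2x2, n_classified)
  lo <- hi <- rep(NA_real_, length(metrics))
  if (ci) {
    for (i in seq_along(metrics)) {
      m <- metrics[i]
      if (m == "prevalence") next # descriptive, not a performance metric
      if (is.na(est[i])) next # undefined metric: no CI, stays NA
      b <- bootstrap_ci(m, truth, pred = pred, values = values,
                        n_boot = n_boot, seed = substream_seed(seed, m))
      lo[i] <- b$ci_low; hi[i] <- b$ci_high
    }
  }
  out <- tibble::tibble(metric = metrics, estimate = unname(est),
                        ci_low = lo, ci_high = hi, n = ns)
  attr(out, "counts") <- counts
  out
}
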