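#' Empirical cutoff at a target specificity, sensitivity, or Youden point
#'
#' Scans candidate thresholds — the midpoints between consecutive distinct
#' observed values, with infinite sentinels at both ends — under the
#' convention that a subject is test-positive when the marker value is
#' strictly greater than the cutoff. `"at_specificity"` returns the
#' threshold achieving specificity at or above `target_level` with maximal
#' sensitivity; `"at_sensitivity"` the threshold achieving sensitivity at
#' or above `target_level` with maximal specificity; `"youden"` maximizes
#' sensitivity + specificity - 1 (ties broken toward higher specificity).
#'
#' @param values Numeric marker values.
#' @param labels Reference-standard labels (logical, 0/1 or
#'   `"positive"`/`"negative"`); positives are expected to run higher.
#' @param method One of `"at_specificity"`, `"at_sensitivity"`, `"youden"`.
#' @param target_level Target specificity or sensitivity in (0, 1);
#'   ignored for `"youden"`.
#' @return A list with `cutoff`, `achieved_sens`, `achieved_spec` on the
#'   input data.
#' @export
#' @examples
#' v <- c(1:10, 8:17)
#' l <- rep(c(0, 1), each = 10)
#' empirical_cutoff(v, l, "at_specificity", 0.90)$cutoff # 9.5
empirical_cutoff <- function(values, labels,
                             method = c("at_specificity", "at_sensitivity",
                                        "youden"),
                             target_level = 0.95) {
  method <- match.arg(method)
  pos <- as_positive(labels)
  keep <- !is.na(values) & !is.na(pos)
  values <- values[keep]; pos <- pos[keep]
  assert_two_classes(pos, "cutoff derivation data")
  if (method != "youden" &&
      (target_level <= 0 || target_level >= 1)) {
    stop("target_level must be in (0, 1)", call. = FALSE)
  }
  v <- sort(unique(values))
  if (length(v) < 2) {
    stop("all marker values identical: no discriminating threshold",
         call. = FALSE)
  }
  cand <- c(-Inf, (v[-1] + v[-length(v)]) / 2, Inf)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  # positive iff value > c. Candidate i sits just above the i-th distinct
  # value, so counts at or below each candidate are cumulative counts over
  # the distinct values (0 at the -Inf sentinel).
  slot <- match(values, v)
  cum_pos <- c(0, cumsum(tabulate(slot[pos], length(v))))
  cum_neg <- c(0, cumsum(tabulate(slot[!pos], length(v))))
  sens <- (n_pos - cum_pos) / n_pos
  spec <- cum_neg / n_neg
  idx <- switch(
    method,
    at_specificity = {
      ok <- which(spec >= target_level)
      # sens is non-increasing: ties in maximal sensitivity are broken
      # toward the larger threshold, i.e. the higher specificity
      best <- ok[sens[ok] >= max(sens[ok]) - 1e-12]
      best[which.max(spec[best])]
    },
    at_sensitivity = {
      ok <- which(sens >= target_level)
      # sens is non-increasing in the threshold; take the largest threshold
      # meeting the target, which maximizes specificity
      ok[which.max(spec[ok])]
    },
    youden = {
      j <- sens + spec - 1
      best <- which(j >= max(j) - 1e-12)
      best[which.max(spec[best])]
    }
  )
  if (length(idx) == 0 || is.na(idx)) {
    stop("no threshold attains the requested target", call. = FALSE)
  }
  list(cutoff = cand[idx], achieved_sens = sens[idx],
       achieved_spec = spec[idx])
}

#' Bootstrap cutoff estimate with percentile confidence interval
#'
#' Resamples subjects with replacement `n_boot` times, derives the
#' [empirical_cutoff()] in each resample, and returns the mean of the
#' bootstrap cutoffs as the point estimate with the 2.5th/97.5th percentile
#' interval. Resamples that lose one of the classes are redrawn (bounded).
#' The achieved sensitivity and specificity are evaluated by applying the
#' point estimate back to the full derivation data.
#'
#' @inheritParams empirical_cutoff
#' @param n_boot Number of bootstrap iterations (2,000 by default).
#' @param seed Integer seed.
#' @param ci_level Confidence level for the percentile interval.
#' @return An object of class `cutoff_estimate` with fields `cutoff`,
#'   `ci_low`, `ci_high`, `method`, `target_level`, `n_boot`, `seed`,
#'   `achieved_sens`, `achieved_spec` and the in-sample scan cutoff
#'   `empirical_cutoff`.
#' @export
bootstrap_cutoff <- function(values, labels,
                             method = c("at_specificity", "at_sensitivity",
                                        "youden"),
                             target_level = 0.95, n_boot = 2000L,
                             seed = 1L, ci_level = 0.95) {
  method <- match.arg(method)
  pos <- as_positive(labels)
  keep <- !is.na(values) & !is.na(pos)
  values <- values[keep]; pos <- pos[keep]
  assert_two_classes(pos, "cutoff derivation data")
  stopifnot(n_boot >= 1)
  n <- length(values)
  boots <- withr::with_seed(seed, {
    out <- numeric(n_boot)
    attempts_left <- 100 * n_boot
    for (b in seq_len(n_boot)) {
      repeat {
        attempts_left <- attempts_left - 1
        if (attempts_left < 0) {
          stop("exhausted bootstrap redraws: resamples keep losing a class",
               call. = FALSE)
        }
        idx <- sample.int(n, n, replace = TRUE)
        if (any(pos[idx]) && any(!pos[idx])) break
      }
      out[b] <- empirical_cutoff(values[idx], pos[idx], method,
                                 target_level)$cutoff
    }
    out
  })
  est <- mean(boots)
  ci <- percentile_ci(boots, ci_level)
  structure(
    list(cutoff = est, ci_low = ci[["ci_low"]], ci_high = ci[["ci_high"]],
         method = method,
         target_level = if (method == "youden") NA_real_ else target_level,
         n_boot = as.integer(n_boot), seed = as.integer(seed),
         achieved_sens = mean(values[pos] > est),
         achieved_spec = mean(values[!pos] <= est),
         empirical_cutoff = empirical_cutoff(values, pos, method,
                                             target_level)$cutoff),
    class = "cutoff_estimate"
  )
}

#' @export
print.cutoff_estimate <- function(x, ...) {
  lvl <- if (is.na(x$target_level)) "" else sprintf(" @ %.2f", x$target_level)
  cat(sprintf("Bootstrap cutoff (%s%s): %.4g (95%% CI %.4g-%.4g)\n",
              x$method, lvl, x$cutoff, x$ci_low, x$ci_high))
  cat(sprintf("  achieved sens %.3f / spec %.3f on derivation data; n_boot = %d\n",
              x$achieved_sens, x$achieved_spec, x$n_boot))
  invisible(x)
}

#' Derive the single and dual cutoffs for a marker on a derivation cohort
#'
#' Bundles three [bootstrap_cutoff()] runs: the single cutoff at 90%
#' specificity (with maximized sensitivity), and the dual-cutoff pair at
#' 95% sensitivity (lower) and 95% specificity (upper). Values between the
#' lower and upper cutoffs are classified as intermediate by
#' [classify_triage()].
#'
#' @inheritParams bootstrap_cutoff
#' @param marker_name,derivation_cohort Provenance labels stored on the set.
#' @param single_specificity Target specificity of the single cutoff.
#' @param dual_sensitivity,dual_specificity Targets for the lower and upper
#'   cutoffs.
#' @param youden Also derive a Youden-index single cutoff (sensitivity
#'   analysis).
#' @return An object of class `cutoff_set` with elements `single`, `lower`,
#'   `upper` (and optionally `youden`), each a `cutoff_estimate`.
#' @export
derive_cutoff_set <- function(values, labels, marker_name = "marker",
                              derivation_cohort = "derivation",
                              single_specificity = 0.90,
                              dual_sensitivity = 0.95,
                              dual_specificity = 0.95,
                              youden = FALSE, n_boot = 2000L, seed = 1L) {
  single <- bootstrap_cutoff(values, labels, "at_specificity",
                             single_specificity, n_boot,
                             substream_seed(seed, "single"))
  lower <- bootstrap_cutoff(values, labels, "at_sensitivity",
                            dual_sensitivity, n_boot,
                            substream_seed(seed, "lower"))
  upper <- bootstrap_cutoff(values, labels, "at_specificity",
                            dual_specificity, n_boot,
                            substream_seed(seed, "upper"))
  out <- list(single = single, lower = lower, upper = upper,
              marker_name = marker_name,
              derivation_cohort = derivation_cohort)
  if (youden) {
    out$youden <- bootstrap_cutoff(values, labels, "youden", NA, n_boot,
                                   substream_seed(seed, "youden"))
  }
  if (lower$cutoff > upper$cutoff) {
    warning("degenerate cutoff set: lower cutoff exceeds upper cutoff",
            call. = FALSE)
  }
  structure(out, class = "cutoff_set")
}

#' @export
print.cutoff_set <- function(x, ...) {
  cat(sprintf("Cutoff set for %s (derived in %s)\n", x$marker_name,
              x$derivation_cohort))
  cat(sprintf("  single (>): %.4g [%.4g, %.4g]\n", x$single$cutoff,
              x$single$ci_low, x$single$ci_high))
  cat(sprintf("  lower  (<): %.4g [%.4g, %.4g]\n", x$lower$cutoff,
              x$lower$ci_low, x$lower$ci_high))
  cat(sprintf("  upper  (>): %.4g [%.4g, %.4g]\n", x$upper$cutoff,
              x$upper$ci_low, x$upper$ci_high))
  if (!is.null(x$youden)) {
    cat(sprintf("  youden (>): %.4g [%.4g, %.4g]\n", x$youden$cutoff,
                x$youden$ci_low, x$youden$ci_high))
  }
  invisible(x)
}

#' Serialize / restore a cutoff set
#'
#' Cutoff sets derived on one cohort are frozen to a structured text block
#' (JSON) so evaluation cohorts can consume exactly the same decimal values.
#'
#' @param x A `cutoff_set`.
#' @param path File path.
#' @return `read_cutoff_set()` returns the restored `cutoff_set`.
#' @export
write_cutoff_set <- function(x, path) {
  stopifnot(inherits(x, "cutoff_set"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE, force = TRUE)
  invisible(path)
}

#' @rdname write_cutoff_set
#' @export
read_cutoff_set <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in intersect(c("single", "lower", "upper", "youden"), names(x))) {
    x[[f]] <- structure(as.list(x[[f]]), class = "cutoff_estimate")
  }
  structure(x, class = "cutoff_set")
}
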