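# Independent oracles, deliberately written as direct brute-force
# computations with no shared code with the package internals.

# exhaustive threshold scan: every midpoint between consecutive distinct
# values plus infinite sentinels, counting each class directly
brute_force_cutoff <- function(values, labels, method, target = NULL) {
  pos <- labels == 1 | labels == TRUE | labels == "positive"
  v <- sort(unique(values))
  cand <- c(-Inf, (head(v, -1) + tail(v, -1)) / 2, Inf)
  best <- NULL
  for (cc in cand) {
    sens <- sum(values[pos] > cc) / sum(pos)
    spec <- sum(values[!pos] <= cc) / sum(!pos)
    keep <- switch(method,
      at_specificity = spec >= target,
      at_sensitivity = sens >= target,
      youden = TRUE)
    if (!keep) next
    score <- switch(method,
      at_specificity = sens,
      at_sensitivity = spec,
      youden = sens + spec - 1)
    better <- is.null(best) || score > best$score + 1e-12 ||
      (abs(score - best$score) <= 1e-12 && spec > best$spec + 1e-12)
    if (better) best <- list(cutoff = cc, score = score, spec = spec)
  }
  best$cutoff
}

# trapezoidal area under the empirical ROC curve, built point by point
trapezoid_auc <- function(values, labels) {
  pos <- labels == 1 | labels == TRUE | labels == "positive"
  thr <- c(Inf, sort(unique(values), decreasing = TRUE), -Inf)
  fpr <- sapply(thr, function(t) mean(values[!pos] >= t))
  tpr <- sapply(thr, function(t) mean(values[pos] >= t))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# canonical worked separable example: negatives 1..10, positives 8..17
sep_example <- function() {
  list(values = c(1:10, 8:17), labels = rep(c(0, 1), each = 10))
}

# random small two-class dataset with ties (integer-valued marker)
random_small_data <- function(n_max = 200) {
  n <- sample(10:n_max, 1)
  n_pos <- sample(3:(n - 3), 1)
  values <- sample(0:30, n, replace = TRUE) +
    sample(c(0, 0.5), n, replace = TRUE)
  labels <- rep(c(1, 0), c(n_pos, n - n_pos))
  # inject a signal so targets are attainable but imperfect
  values[labels == 1] <- values[labels == 1] + sample(0:10, 1)
  list(values = values, labels = labels)
}
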