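#' Derive a biomarker cutoff from a two-component Gaussian mixture
#'
#' Fits a univariate two-component Gaussian mixture by expectation-
#' maximization (unequal variances, free weights) and returns the point
#' between the two component means at which posterior membership
#' probabilities are equal. This is the standard way to dichotomize a
#' bimodal biomarker — here the CSF Ab42:p-tau181 ratio — without an
#' external gold standard; the lower-mean component is the pathological
#' (low-ratio) side.
#'
#' Initialization is a split at the median plus `n_restarts` random
#' quantile splits, keeping the solution with the best log-likelihood;
#' all randomness is governed by `seed`.
#'
#' @param values Numeric vector (at least 50 values, at least 2 distinct).
#' @param seed Integer seed for the random restarts.
#' @param log_scale Fit on `log(values)` instead of the raw scale (the
#'   returned cutoff is then back-transformed). Default `FALSE`: the
#'   reference cutoff is conventionally quoted on the raw ratio scale.
#' @param n_restarts Number of random restarts beyond the median split.
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @param error_on_failure Error (rather than flag) when EM fails to
#'   converge.
#' @return An object of class `gmm_cutoff`: `cutoff`, `component_means`,
#'   `component_sds`, `component_weights` (ascending by mean), `n_used`,
#'   `converged`, `log_likelihood`, `log_scale`.
#' @export
#' @examples
#' x <- c(rnorm(200, 8, 2), rnorm(200, 30, 10))
#' fit_gmm_cutoff(x, seed = 1)$cutoff
fit_gmm_cutoff <- function(values, seed = 1L, log_scale = FALSE,
                           n_restarts = 10L, max_iter = 5000L, tol = 1e-12,
                           error_on_failure = FALSE) {
  values <- values[!is.na(values)]
  if (length(values) < 50) {
    stop("need at least 50 values to fit a mixture", call. = FALSE)
  }
  if (length(unique(values)) < 2) {
    stop("need at least 2 distinct values", call. = FALSE)
  }
  x <- if (log_scale) {
    if (any(values <= 0)) stop("log_scale requires positive values",
                               call. = FALSE)
    log(values)
  } else {
    values
  }
  fit <- withr::with_seed(seed, em_best_fit(x, n_restarts, max_iter, tol))
  if (!fit$converged && error_on_failure) {
    stop("EM did not converge within ", max_iter, " iterations",
         call. = FALSE)
  }
  pooled_sd <- sqrt(mean(fit$sigma^2))
  if (abs(diff(fit$mu)) < 1e-6 * pooled_sd) {
    stop("mixture is not identifiable: fitted component means coincide",
         call. = FALSE)
  }
  cut_x <- equal_posterior_point(fit$mu, fit$sigma, fit$w)
  structure(
    list(
      cutoff = if (log_scale) exp(cut_x) else cut_x,
      component_means = if (log_scale) exp(fit$mu) else fit$mu,
      component_sds = fit$sigma,
      component_weights = fit$w,
      n_used = length(x),
      converged = fit$converged,
      log_likelihood = fit$loglik,
      log_scale = log_scale
    ),
    class = "gmm_cutoff"
  )
}

#' @export
print.gmm_cutoff <- function(x, ...) {
  cat("Two-component Gaussian mixture cutoff\n")
  cat(sprintf("  cutoff: %.4g  (n = %d, %s)\n", x$cutoff, x$n_used,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  components: mean %.4g sd %.4g w %.3f | mean %.4g sd %.4g w %.3f\n",
              x$component_means[1], x$component_sds[1], x$component_weights[1],
              x$component_means[2], x$component_sds[2], x$component_weights[2]))
  invisible(x)
}

em_fit_once <- function(x, split, max_iter, tol) {
  below <- x <= split
  if (!any(below) || all(below)) return(NULL)
  mu <- c(mean(x[below]), mean(x[!below]))
  sigma <- pmax(c(sd(x[below]), sd(x[!below])), 1e-8 * sd(x), 1e-12)
  sigma[is.na(sigma)] <- sd(x)
  w <- c(mean(below), 1 - mean(below))
  loglik <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * dnorm(x, mu[1], sigma[1])
    d2 <- w[2] * dnorm(x, mu[2], sigma[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    new_loglik <- sum(log(tot))
    r <- d1 / tot
    w <- c(mean(r), 1 - mean(r))
    if (any(w < 1e-10)) return(NULL) # component collapsed
    mu <- c(sum(r * x) / sum(r), sum((1 - r) * x) / sum(1 - r))
    sigma <- sqrt(c(sum(r * (x - mu[1])^2) / sum(r),
                    sum((1 - r) * (x - mu[2])^2) / sum(1 - r)))
    sigma <- pmax(sigma, 1e-8 * sd(x))
    if (is.finite(loglik) &&
        abs(new_loglik - loglik) < tol * (1 + abs(new_loglik))) {
      converged <- TRUE
      loglik <- new_loglik
      break
    }
    loglik <- new_loglik
  }
  ord <- order(mu)
  list(mu = mu[ord], sigma = sigma[ord], w = w[ord], loglik = loglik,
       converged = converged)
}

em_best_fit <- function(x, n_restarts, max_iter, tol) {
  splits <- c(stats::median(x),
              quantile(x, runif(n_restarts, 0.1, 0.9), names = FALSE))
  best <- NULL
  for (s in splits) {
    fit <- em_fit_once(x, s, max_iter, tol)
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) {
      best <- fit
    }
  }
  if (is.null(best)) {
    stop("EM failed from every initialization", call. = FALSE)
  }
  best
}

#' Equal-posterior point between two Gaussian components
#'
#' Solves `w1 * dnorm(x, mu1, s1) = w2 * dnorm(x, mu2, s2)` for the root
#' lying between the two component means (closed-form quadratic in `x`,
#' linear when the variances are equal).
#'
#' @param mu,sigma,w Length-2 component means, SDs and weights.
#' @return The crossing point between the means.
#' @export
equal_posterior_point <- function(mu, sigma, w) {
  stopifnot(length(mu) == 2, length(sigma) == 2, length(w) == 2,
            all(sigma > 0), all(w > 0))
  lo <- min(mu); hi <- max(mu)
  # log w1 - log s1 - (x-mu1)^2/(2 s1^2) = log w2 - log s2 - (x-mu2)^2/(2 s2^2)
  a <- 1 / (2 * sigma[2]^2) - 1 / (2 * sigma[1]^2)
  b <- mu[1] / sigma[1]^2 - mu[2] / sigma[2]^2
  cc <- mu[2]^2 / (2 * sigma[2]^2) - mu[1]^2 / (2 * sigma[1]^2) +
    log(w[1] / w[2]) + log(sigma[2] / sigma[1])
  if (abs(a) < 1e-14) {
    root <- -cc / b
    if (root < lo - 1e-9 || root > hi + 1e-9) {
      stop("no equal-posterior point between the component means",
           call. = FALSE)
    }
    return(root)
  }
  disc <- b^2 - 4 * a * cc
  if (disc < 0) stop("no real equal-posterior point", call. = FALSE)
  roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  inside <- roots[roots >= lo - 1e-9 & roots <= hi + 1e-9]
  if (length(inside) == 0) {
    stop("no equal-posterior point between the component means",
         call. = FALSE)
  }
  inside[1]
}

#' Configuration of the AD-pathology reference standard
#'
#' @param outcome Which CSF outcome defines AD pathology:
#'   `"csf_ab42_ptau181_gmm"` (cutoff derived by [fit_gmm_cutoff()] on the
#'   pooled CSF Ab42:p-tau181 ratios; positivity is ratio strictly below the
#'   cutoff), `"csf_ab42_ptau181_fixed"` (fixed cutoff, default 11.94,
#'   strict `<`), or `"csf_ab42_40_fixed"` (fixed cutoff, default 0.072,
#'   positivity `<=` the cutoff).
#' @param fixed_cutoff Cutoff for the fixed-outcome modes; defaults to
#'   11.94 (Ab42:p-tau181) or 0.072 (Ab42:40).
#' @param pet_fallback Use the amyloid-PET visual read for subjects without
#'   CSF.
#' @param exclude_pet_labeled Sensitivity analysis: leave subjects without
#'   CSF as `"unknown"` even when a PET read is available.
#' @return An object of class `reference_config`.
#' @export
reference_config <- function(outcome = c("csf_ab42_ptau181_gmm",
                                         "csf_ab42_ptau181_fixed",
                                         "csf_ab42_40_fixed"),
                             fixed_cutoff = NULL, pet_fallback = TRUE,
                             exclude_pet_labeled = FALSE) {
  outcome <- match.arg(outcome)
  if (is.null(fixed_cutoff)) {
    fixed_cutoff <- switch(outcome,
                           csf_ab42_ptau181_fixed = 11.94,
                           csf_ab42_40_fixed = 0.072,
                           NA_real_)
  }
  if (!is.na(fixed_cutoff) && fixed_cutoff <= 0) {
    stop("fixed_cutoff must be > 0", call. = FALSE)
  }
  structure(
    list(outcome = outcome, fixed_cutoff = fixed_cutoff,
         pet_fallback = pet_fallback,
         exclude_pet_labeled = exclude_pet_labeled),
    class = "reference_config"
  )
}

#' Assign the AD-pathology reference label
#'
#' Labels each subject `"positive"`, `"negative"` or `"unknown"` from the
#' configured CSF outcome, falling back to the amyloid-PET visual read when
#' CSF is missing (if enabled). Positivity is a strictly lower CSF
#' Ab42:p-tau181 ratio (`< cutoff`) or a CSF Ab42:40 ratio at or below the
#' cutoff (`<=`).
#'
#' @param cohort A cohort tibble (columns `csf_ab42_ptau181`,
#'   `csf_ab42_40`, `pet_visual_read` as applicable).
#' @param config A [reference_config()].
#' @param gmm A [fit_gmm_cutoff()] result; required for the GMM outcome.
#' @return Character vector `"positive"`/`"negative"`/`"unknown"`.
#' @export
assign_ad_status <- function(cohort, config = reference_config(),
                             gmm = NULL) {
  stopifnot(inherits(config, "reference_config"))
  if (config$outcome == "csf_ab42_ptau181_gmm") {
    if (is.null(gmm)) {
      stop("the GMM outcome requires a fitted `gmm` cutoff", call. = FALSE)
    }
    cutoff <- gmm$cutoff
  } else {
    cutoff <- config$fixed_cutoff
  }
  if (config$outcome == "csf_ab42_40_fixed") {
    ratio <- cohort$csf_ab42_40
    is_pos <- ratio <= cutoff
  } else {
    ratio <- cohort$csf_ab42_ptau181
    is_pos <- ratio < cutoff
  }
  out <- ifelse(is.na(ratio), NA_character_,
                ifelse(is_pos, "positive", "negative"))
  need_pet <- is.na(ratio)
  if (config$pet_fallback && !config$exclude_pet_labeled &&
      "pet_visual_read" %in% names(cohort)) {
    pet <- cohort$pet_visual_read
    use <- need_pet & !is.na(pet)
    out[use] <- pet[use]
  }
  out[is.na(out)] <- "unknown"
  out
}
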