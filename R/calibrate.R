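#' Solve class-conditional log-normal parameters from pooled moments
#'
#' Biomarker concentrations are modelled as log-normal within each AD
#' pathology class, with a shared log-scale standard deviation. Given the
#' pooled (mixture) mean and SD of a marker in a cohort, the prevalence of
#' AD pathology, and the discriminative performance the marker should have,
#' this solves for the two class-conditional distributions.
#'
#' On the log scale the two classes are `N(mu_neg, sigma^2)` and
#' `N(mu_pos, sigma^2)`; the AUC of such a pair is
#' `Phi((mu_pos - mu_neg) / (sigma * sqrt(2)))` (AUC is invariant under the
#' monotone exp transform), which pins down the class separation for a
#' given `sigma`. The remaining two unknowns are solved so that the
#' analytic mixture mean and SD equal the targets.
#'
#' @param mean,sd Target pooled mean and SD on the concentration scale.
#' @param prevalence Proportion of AD-positive subjects in the pool.
#' @param auc Target AUC of the marker for AD pathology (positives higher).
#' @return A list with `meanlog_neg`, `meanlog_pos`, `sdlog` (shared), and
#'   the implied class-conditional means on the concentration scale.
#' @export
#' @examples
#' p <- lognormal_mixture_calibrate(0.36, 0.33, 0.454, 0.95)
#' lognormal_mixture_moments(p$meanlog_neg, p$meanlog_pos, p$sdlog, 0.454)
lognormal_mixture_calibrate <- function(mean, sd, prevalence, auc) {
  stopifnot(mean > 0, sd > 0, prevalence > 0, prevalence < 1,
            auc >= 0.5, auc < 1)
  z <- qnorm(auc)
  target_m2 <- sd^2 + mean^2
  excess <- function(sigma) {
    delta <- sqrt(2) * sigma * z
    r <- exp(delta)
    denom <- (1 - prevalence) + prevalence * r
    a <- mean / (exp(sigma^2 / 2) * denom)
    m2 <- exp(2 * sigma^2) * a^2 * ((1 - prevalence) + prevalence * r^2)
    m2 - target_m2
  }
  sigma <- uniroot(excess, c(1e-4, 4), tol = 1e-12)$root
  delta <- sqrt(2) * sigma * z
  denom <- (1 - prevalence) + prevalence * exp(delta)
  mu_neg <- log(mean) - sigma^2 / 2 - log(denom)
  list(
    meanlog_neg = mu_neg,
    meanlog_pos = mu_neg + delta,
    sdlog = sigma,
    mean_neg = exp(mu_neg + sigma^2 / 2),
    mean_pos = exp(mu_neg + delta + sigma^2 / 2)
  )
}

#' Analytic moments of a two-component log-normal mixture
#'
#' @param meanlog_neg,meanlog_pos Log-scale locations of the AD-negative and
#'   AD-positive components.
#' @param sdlog Log-scale SD; either a single shared value or a vector
#'   `c(neg, pos)`.
#' @param prevalence Mixing weight of the positive component.
#' @return A list with the mixture `mean` and `sd` on the concentration scale.
#' @export
lognormal_mixture_moments <- function(meanlog_neg, meanlog_pos, sdlog,
                                      prevalence) {
  sdlog <- rep_len(sdlog, 2L)
  m1 <- c(exp(meanlog_neg + sdlog[1]^2 / 2),
          exp(meanlog_pos + sdlog[2]^2 / 2))
  m2 <- c(exp(2 * meanlog_neg + 2 * sdlog[1]^2),
          exp(2 * meanlog_pos + 2 * sdlog[2]^2))
  w <- c(1 - prevalence, prevalence)
  mixture_mean <- sum(w * m1)
  mixture_m2 <- sum(w * m2)
  list(mean = mixture_mean, sd = sqrt(mixture_m2 - mixture_mean^2))
}
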