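#' Derive a reproducible sub-stream seed from a global seed
#'
#' Pipeline stages draw their randomness from independent sub-streams so
#' that each stage is reproducible on its own. The sub-stream seed is a
#' deterministic hash of the global seed and a stage label, kept within
#' the 32-bit signed integer range R requires of `set.seed()`.
#'
#' @param seed Integer global seed.
#' @param label Character stage label (e.g. `"cutoffs/plasma_ptau217"`).
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' substream_seed(1L, "cutoffs")
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(label)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

# normalize a truth vector to logical (TRUE = AD pathology positive)
as_positive <- function(truth) {
  if (is.logical(truth)) return(truth)
  if (is.numeric(truth)) {
    bad <- !truth %in% c(0, 1, NA)
    if (any(bad)) stop("numeric truth labels must be 0/1", call. = FALSE)
    return(truth == 1)
  }
  x <- tolower(as.character(truth))
  out <- rep(NA, length(x))
  out[x %in% c("positive", "pos", "1", "true", "yes")] <- TRUE
  out[x %in% c("negative", "neg", "0", "false", "no")] <- FALSE
  unknown <- !is.na(x) & is.na(out)
  if (any(unknown)) {
    stop("unrecognized truth labels: ",
         paste(unique(x[unknown]), collapse = ", "), call. = FALSE)
  }
  out
}

assert_two_classes <- function(truth, what = "input") {
  pos <- as_positive(truth)
  if (!any(pos, na.rm = TRUE) || !any(!pos, na.rm = TRUE)) {
    stop(what, " must contain both AD-positive and AD-negative subjects",
         call. = FALSE)
  }
  invisible(pos)
}

percentile_ci <- function(x, level = 0.95) {
  alpha <- (1 - level) / 2
  q <- quantile(x, c(alpha, 1 - alpha), names = FALSE, na.rm = TRUE)
  c(ci_low = q[1], ci_high = q[2])
}
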