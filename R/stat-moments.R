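# The 14-moment statistical feature extractor.
#
# Conventions (the usual defaults of numeric computing environments):
# sample standard deviation (n - 1); moment-based biased skewness; kurtosis
# not excess (normal -> 3).  The four entropies operate on the normalized
# energy distribution p_i = x_i^2 / sum(x^2); all-zero inputs yield zero for
# every entropy term.

#' Names of the 14 statistical moments, in extraction order
#' @return Character vector of length 14.
#' @export
stat_feature_names <- function() {
  c(
    "average", "maximum", "minimum", "median", "sd", "kurtosis", "skewness",
    "range", "rms", "max_abs_dev", "shannon_entropy", "sure_entropy",
    "tsallis_entropy", "log_entropy"
  )
}

#' 14 statistical moments of a signal
#'
#' Computes, in order: average, maximum, minimum, median, standard deviation
#' (sample, n - 1), kurtosis (biased, not excess), skewness (biased), range,
#' root mean square, maximum absolute deviation from the mean, Shannon
#' entropy, sure entropy, Tsallis entropy and log-energy entropy.
#'
#' Entropy conventions: with `p_i = x_i^2 / sum(x^2)`, Shannon is
#' `-sum(p_i log p_i)` (0 log 0 = 0); Tsallis is `(1 - sum(p_i^q))/(q - 1)`;
#' sure is `sum(min(x_i^2, eps^2))`; log-energy is `sum(log(x_i^2))` with
#' zero samples contributing 0.
#'
#' @param x Numeric vector, length >= 2, finite values.
#' @param tsallis_q Tsallis order (default 2).
#' @param sure_eps Sure-entropy threshold (default 3).
#' @return Named numeric vector of length 14 (names from
#'   [stat_feature_names()]).
#' @examples
#' statistical_features(c(1, 2, 3, 4))[["rms"]]  # sqrt(7.5)
#' @export
statistical_features <- function(x, tsallis_q = 2, sure_eps = 3) {
  if (length(x) < 2) stop("need at least 2 samples (standard deviation undefined)")
  .check_signal(x, 2, "x")
  m <- mean(x)
  centred <- x - m
  m2 <- mean(centred^2)
  kurt <- if (m2 > 0) mean(centred^4) / m2^2 else NaN
  skew <- if (m2 > 0) mean(centred^3) / m2^1.5 else NaN

  x2 <- x^2
  tot <- sum(x2)
  if (tot > 0) {
    p <- x2 / tot
    pp <- p[p > 0]
    shannon <- -sum(pp * log(pp))
    tsallis <- (1 - sum(p^tsallis_q)) / (tsallis_q - 1)
  } else {
    shannon <- 0
    tsallis <- 0
  }
  loge <- sum(log(x2[x2 > 0]))
  sure <- sum(pmin(x2, sure_eps^2))

  out <- c(
    m, max(x), min(x), stats::median(x), stats::sd(x), kurt, skew,
    max(x) - min(x), sqrt(mean(x2)), max(abs(centred)), shannon, sure,
    tsallis, loge
  )
  names(out) <- stat_feature_names()
  out
}
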