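# Multilevel discrete wavelet transform (symlet-4, low-pass cascade).
#
# Only the approximation (low-pass) bands feed the downstream feature
# extractors; detail coefficients are computed (and reconstructable) but
# discarded by mdwt_lowpass().  Boundary handling is half-point symmetric
# extension, so a band of length l maps to floor((l - 1)/2) + F/2 with
# filter length F = 8.

# symlet-4 decomposition / reconstruction filters (orthonormal, F = 8)
.sym4 <- list(
  dec_lo = c(
    -0.075765714789273325, -0.02963552764599851, 0.49761866763201545,
    0.80373875180591614, 0.29785779560527736, -0.099219543576847216,
    -0.012603967262037833, 0.032223100604042702
  )
)
.sym4$dec_hi <- rev(.sym4$dec_lo) * c(-1, 1) # quadrature mirror
.sym4$rec_lo <- rev(.sym4$dec_lo)
.sym4$rec_hi <- rev(.sym4$dec_hi)

.sym_extend <- function(x, m) {
  # half-point symmetric extension by m samples each side:
  # [x_m..x_1 | x | x_n..x_{n-m+1}], reflecting repeatedly for short inputs
  n <- length(x)
  pos <- (1L - m):(n + m)
  q <- (pos - 1L) %% (2L * n)
  idx <- ifelse(q < n, q + 1L, 2L * n - q)
  x[idx]
}

.conv_valid <- function(x, h) {
  F <- length(h)
  stats::embed(x, F) %*% h # row t = sum_j h[j] * x[t + F - j]
}

#' Single-level discrete wavelet transform (symlet 4)
#'
#' One analysis step with half-point symmetric boundary extension.  Output
#' length is `floor((n - 1)/2) + 4` for both bands.
#'
#' @param x Numeric vector, length >= 2.
#' @param wavelet Only `"sym4"` is supported.
#' @return List with `a` (approximation) and `d` (detail) coefficients.
#' @seealso [idwt_sym()], [mdwt_lowpass()]
#' @export
dwt_sym <- function(x, wavelet = "sym4") {
  if (!identical(wavelet, "sym4")) stop("only the sym4 wavelet is supported")
  if (length(x) < 2) stop("signal too short for a DWT step")
  F <- 8L
  ext <- .sym_extend(as.numeric(x), F - 1L)
  keep <- seq(2L, length(ext) - F + 1L, by = 2L)
  list(
    a = as.numeric(.conv_valid(ext, .sym4$dec_lo)[keep]),
    d = as.numeric(.conv_valid(ext, .sym4$dec_hi)[keep])
  )
}

#' Single-level inverse discrete wavelet transform (symlet 4)
#'
#' Exact inverse of [dwt_sym()]: upsamples both bands, filters with the
#' reconstruction pair and crops the central `n` samples.
#'
#' @param a,d Approximation and detail coefficients from [dwt_sym()].
#' @param n Length of the original signal.
#' @param wavelet Only `"sym4"` is supported.
#' @return Numeric vector of length `n`.
#' @export
idwt_sym <- function(a, d, n, wavelet = "sym4") {
  if (!identical(wavelet, "sym4")) stop("only the sym4 wavelet is supported")
  if (length(a) != length(d)) stop("a and d must have equal length")
  F <- 8L
  up <- function(c) {
    u <- numeric(2L * length(c) - 1L)
    u[seq(1L, length(u), by = 2L)] <- c
    u
  }
  yfull <- stats::convolve(up(a), rev(.sym4$rec_lo), type = "open") +
    stats::convolve(up(d), rev(.sym4$rec_hi), type = "open")
  if (n > length(yfull) - (F - 2L)) stop("n inconsistent with coefficient length")
  yfull[(F - 1L):(F - 2L + n)]
}

#' Multilevel low-pass wavelet band cascade
#'
#' Applies [dwt_sym()] repeatedly to the running approximation band,
#' returning the `levels` approximation sequences (detail coefficients are
#' discarded).  Every returned band must be long enough (>= 11 samples) to
#' feed the GHPat extractor; a too-short cascade fails with the first level
#' that violates this.
#'
#' @param signal Numeric vector (a 7500-sample 15-s segment at 500 Hz
#'   comfortably supports the default depth).
#' @param levels Number of cascade levels (default 7).
#' @param wavelet Only `"sym4"` is supported.
#' @return An object of class `wavelet_bands`: list with `lowpass` (list of
#'   `levels` coefficient vectors), `wavelet_name`, `levels`.
#' @examples
#' b <- mdwt_lowpass(rnorm(7500))
#' lengths(b$lowpass)  # 3753 1880 943 475 241 124 65
#' @export
mdwt_lowpass <- function(signal, levels = 7L, wavelet = "sym4") {
  .check_signal(signal, 11, "signal")
  levels <- as.integer(levels)
  if (levels < 1L) stop("levels must be >= 1")
  low <- vector("list", levels)
  cur <- as.numeric(signal)
  for (k in seq_len(levels)) {
    cur <- dwt_sym(cur, wavelet)$a
    if (length(cur) < 11L) {
      stop("low-pass band at level ", k, " has fewer than 11 samples; ",
           "input too short for ", levels, "-level decomposition")
    }
    low[[k]] <- cur
  }
  structure(
    list(lowpass = low, wavelet_name = wavelet, levels = levels),
    class = "wavelet_bands"
  )
}
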