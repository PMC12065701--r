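# GHPat: quantum-inspired textural feature extraction.
#
# Every overlapping 11-sample block of a 1-D signal is encoded by one of the
# seven directed Goldner-Harary subgraphs.  The subgraph is chosen per block
# by a forward-forward fitness function: the local mean over each subgraph's
# node set is compared (L1) with the whole-signal mean and the closest wins.
# The eight directed edges of the winner yield an 8-bit code
# (bit q = 1 iff value[source] - value[target] >= 0), and the histogram of
# the per-block codes is the 256-length textural feature vector.

.check_signal <- function(signal, min_len, what = "signal") {
  if (!is.numeric(signal)) stop(what, " must be numeric")
  if (anyNA(signal) || any(!is.finite(signal))) {
    stop(what, " contains non-finite values")
  }
  if (length(signal) < min_len) {
    stop(what, " too short for block length ", min_len)
  }
  invisible(TRUE)
}

#' Overlapping 11-sample blocks of a signal
#'
#' Partitions a 1-D signal of length `xi` into its `xi - 10` overlapping
#' blocks of length 11 (stride 1), one per Goldner-Harary node assignment
#' `P1..P11`.
#'
#' @param signal Numeric vector, length >= 11, finite values.
#' @return A `(length(signal) - 10) x 11` numeric matrix; row `i` holds
#'   `signal[i..(i + 10)]` and its row name is the 1-based start index.
#' @examples
#' nrow(make_blocks(sin(1:21)))  # 11 blocks
#' @export
make_blocks <- function(signal) {
  .check_signal(signal, 11)
  n <- length(signal) - 10L
  # embed() yields reversed windows; flip columns to get P1..P11 order
  blocks <- stats::embed(signal, 11)[, 11:1, drop = FALSE]
  dimnames(blocks) <- list(seq_len(n), paste0("P", 1:11))
  blocks
}

#' Per-block subgraph selection by the forward-forward fitness function
#'
#' Computes the seven local means of a block, their L1 distances to the
#' whole-signal mean, and the index of the winning (minimum-distance)
#' subgraph.  Ties go to the lowest subgraph id.
#'
#' @param block Numeric vector of length 11 (one row of [make_blocks()]).
#' @param global_mean Mean of the whole signal the block came from.
#' @param mu_mode `"nodeset"` (default) averages each subgraph over the node
#'   set its edges actually use; `"literal"` reproduces the printed mean
#'   formulas verbatim (the third mean duplicates the first and the seventh
#'   uses subgraph 6's node set).
#' @return A list with `local_means` (7 values), `global_mean`,
#'   `distances` (7 values) and `selected` (winning subgraph id in 1..7).
#' @export
select_subgraph <- function(block, global_mean,
                            mu_mode = c("nodeset", "literal")) {
  mu_mode <- match.arg(mu_mode)
  if (length(block) != 11L) stop("block must have exactly 11 values")
  .check_signal(block, 11, "block")
  mu_h <- as.numeric(.gh_weights[[mu_mode]] %*% block)
  dist_h <- abs(global_mean - mu_h)
  list(
    local_means = mu_h,
    global_mean = global_mean,
    distances = dist_h,
    selected = which.min(dist_h) # which.min returns the first minimum
  )
}

#' Encode one block with one subgraph
#'
#' Bit `q` is 1 iff `block[source_q] - block[target_q] >= 0` for directed
#' edge `q` of the subgraph; the code is `sum(bit_q * 2^(q - 1))`
#' (least-significant bit first).
#'
#' @param block Numeric vector of length 11.
#' @param spec A subgraph id in 1..7 or an element of [gh_subgraphs()].
#' @return Integer code in 0..255.
#' @examples
#' encode_block(rep(1, 11), 1)  # equality counts as 1 on every edge -> 255
#' @export
encode_block <- function(block, spec) {
  if (length(block) != 11L) stop("block must have exactly 11 values")
  h <- if (is.list(spec)) spec$id else as.integer(spec)
  if (is.na(h) || h < 1L || h > 7L) stop("subgraph id must be in 1..7")
  bits <- as.integer(block[.gh_src[h, ]] - block[.gh_tgt[h, ]] >= 0)
  sum(bits * 2L^(0:7))
}

# Vectorized core: codes for all blocks of a signal (the feature-map signal).
.ghpat_codes <- function(signal, mu_mode = "nodeset") {
  blocks <- make_blocks(signal)
  mu <- mean(signal)
  # local means for all blocks x 7 subgraphs, then argmin of |mu - mu_h|
  D <- abs(mu - blocks %*% t(.gh_weights[[mu_mode]]))
  sel <- max.col(-D, ties.method = "first")
  codes <- integer(nrow(blocks))
  pow <- 2L^(0:7)
  for (h in 1:7) {
    rows <- sel == h
    if (!any(rows)) next
    bits <- (blocks[rows, .gh_src[h, ], drop = FALSE] -
               blocks[rows, .gh_tgt[h, ], drop = FALSE]) >= 0
    codes[rows] <- as.integer(bits %*% pow)
  }
  codes
}

#' Feature-map signal of per-block GHPat codes
#'
#' @inheritParams ghpat_transform
#' @return Integer vector of length `length(signal) - 10`, values in 0..255.
#' @export
ghpat_feature_map <- function(signal, mu_mode = c("nodeset", "literal")) {
  mu_mode <- match.arg(mu_mode)
  .ghpat_codes(signal, mu_mode)
}

#' GHPat textural feature vector
#'
#' Full GHPat extraction: overlapping 11-sample blocks, per-block subgraph
#' selection against the whole-signal mean, 8-bit coding by the selected
#' subgraph's directed edges, and the 256-bin histogram of the resulting
#' feature-map signal.
#'
#' @param signal Numeric vector, length >= 11, finite values.
#' @param mu_mode See [select_subgraph()].
#' @return Named integer vector of length 256; element `b + 1` (name `b`)
#'   counts the blocks whose code equals `b`.  The counts sum to
#'   `length(signal) - 10`.
#' @examples
#' h <- ghpat_transform(sin(seq(0, 10, length.out = 100)))
#' sum(h) == 100 - 10
#' @export
ghpat_transform <- function(signal, mu_mode = c("nodeset", "literal")) {
  mu_mode <- match.arg(mu_mode)
  codes <- .ghpat_codes(signal, mu_mode)
  counts <- tabulate(codes + 1L, nbins = 256L)
  names(counts) <- 0:255
  counts
}

#' Classic 1-D local binary pattern histogram (ablation baseline)
#'
#' Standard 1-D LBP: each sample with 4 left and 4 right neighbours is a
#' centre; bit `q` is 1 iff neighbour `q` >= centre, with neighbours ordered
#' left-to-right (the 4 left neighbours give bits 1-4, the 4 right
#' neighbours bits 5-8, least-significant bit first).
#'
#' @param signal Numeric vector, length >= 9, finite values.
#' @return Named integer vector of length 256 summing to
#'   `length(signal) - 8`.
#' @export
lbp1d_baseline <- function(signal) {
  .check_signal(signal, 9)
  win <- stats::embed(signal, 9)[, 9:1, drop = FALSE] # columns: c-4 .. c+4
  centre <- win[, 5]
  bits <- win[, c(1:4, 6:9), drop = FALSE] >= centre
  codes <- as.integer(bits %*% 2L^(0:7))
  counts <- tabulate(codes + 1L, nbins = 256L)
  names(counts) <- 0:255
  counts
}
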