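# Iterative neighbourhood component analysis (INCA) feature selection:
# NCA ranks all features by learned weight, then prefix sizes 50..550 are
# scored by kNN misclassification rate and the best prefix wins.

#' NCA feature ranking
#'
#' Learns per-feature relevance weights by neighbourhood component analysis
#' with a stochastic-gradient solver: distance
#' `d_w(i, j) = sum_r w_r^2 |x_ir - x_jr|`, softmax reference-point kernel
#' `exp(-d/sigma)`, per-sample objective = leave-one-out probability of a
#' same-class reference minus an L2 penalty.  Features are z-scored before
#' fitting; the iteration budget is `ceiling(nos / 2)` passes over the data.
#'
#' @param x Numeric nos x d feature matrix.
#' @param y Integer class per row; at least two classes required.
#' @param seed Integer seed for the visiting order.
#' @param passes Number of SGD passes (default `ceiling(nrow(x) / 2)`).
#' @param lambda Regularization weight (default `1 / nrow(x)`).
#' @param sigma Kernel width on z-scored features.  The default (`NULL`)
#'   sets it to the mean initial pairwise distance, so the softmax kernel
#'   starts neither collapsed onto the nearest neighbour nor flat; weighted
#'   L1 distances grow with the feature count, so a fixed width would not
#'   transfer across dimensionalities.
#' @param alpha0 Initial SGD step size (default 0.1, decaying as
#'   `n / (n + t)` over visits `t`).
#' @return Integer permutation of `1:ncol(x)`, most relevant feature first
#'   (weight ties broken toward the lower index), with the learned weights
#'   in attribute `weights`.
#' @export
nca_rank <- function(x, y, seed = 1L, passes = NULL, lambda = NULL,
                     sigma = NULL, alpha0 = 0.1) {
  x <- as.matrix(x)
  y <- as.integer(y)
  n <- nrow(x)
  if (length(unique(y)) < 2) stop("NCA needs at least two classes")
  if (is.null(passes)) passes <- ceiling(n / 2)
  if (is.null(lambda)) lambda <- 1 / n
  # z-score; constant columns get scale 1 so they stay finite (and irrelevant)
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  if (is.null(sigma)) {
    # mean initial L1 distance (unit weights) over up to 200 sampled pairs
    pairs <- .with_seed(seed + 1L, {
      cbind(sample.int(n, 200, replace = TRUE),
            sample.int(n, 200, replace = TRUE))
    })
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
    sigma <- mean(vapply(seq_len(nrow(pairs)), function(p) {
      sum(abs(xs[pairs[p, 1], ] - xs[pairs[p, 2], ]))
    }, numeric(1)))
    if (!is.finite(sigma) || sigma <= 0) sigma <- ncol(x)
  }
  order_idx <- .with_seed(seed, {
    unlist(lapply(seq_len(passes), function(p) sample.int(n))) - 1L
  })
  w <- .nca_sgd_cpp(t(xs), y, as.integer(order_idx), lambda, sigma, alpha0)
  rank <- order(-(w^2), seq_along(w))
  structure(as.integer(rank), weights = as.numeric(w))
}

#' Iterative NCA prefix search
#'
#' Scores every candidate prefix of the NCA ranking by the stratified
#' 10-fold cross-validated misclassification rate of the weighted kNN
#' classifier, and selects the size with the minimum loss (ties go to the
#' smaller size).
#'
#' @param x,y Feature matrix and classes as in [nca_rank()] (raw, not
#'   z-scored: the kNN stage operates on the original feature scale).
#' @param ranking Feature ranking from [nca_rank()].
#' @param sizes Candidate prefix sizes (default 50:550).  Sizes exceeding
#'   `ncol(x)` are dropped with a warning.
#' @param scorer_seed Seed for the fold assignment.
#' @param k kNN neighbours (default 10, capped at the training-fold size).
#' @param nfold Folds for the internal loss estimate (default 10, capped at
#'   `nrow(x)`).
#' @return An object of class `inca_result`: list with `candidate_sizes`,
#'   `losses`, `best_size`, `selected_indices` and `ranking`.
#' @export
inca_select <- function(x, y, ranking, sizes = 50:550, scorer_seed = 1L,
                        k = 10L, nfold = 10L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  d <- ncol(x)
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes > d)) {
    sizes <- sizes[sizes <= d]
    warning("candidate sizes truncated to the ", d, " available features")
  }
  if (length(sizes) == 0) sizes <- d
  ranking <- as.integer(ranking)
  if (!setequal(ranking, seq_len(d))) stop("ranking must be a permutation of 1..d")
  xr <- x[, ranking[seq_len(max(sizes))], drop = FALSE]
  nfold <- min(nfold, nrow(x))
  foldid <- .stratified_folds(y, nfold, scorer_seed)
  losses <- as.numeric(.inca_scan_cpp(xr, y, sizes, foldid, as.integer(k)))
  best <- which.min(losses) # first minimum -> smaller size on ties
  structure(
    list(candidate_sizes = sizes, losses = losses,
         best_size = sizes[best],
         selected_indices = ranking[seq_len(sizes[best])],
         ranking = ranking),
    class = "inca_result"
  )
}

#' Serialize per-channel selections as JSON
#'
#' @param selections Named list (channel name -> `inca_result`).
#' @param path Output file.
#' @return Invisibly `path`.
#' @export
write_selection_json <- function(selections, path) {
  out <- lapply(names(selections), function(nm) {
    s <- selections[[nm]]
    list(channel = nm, best_size = s$best_size, indices = s$selected_indices)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE)
  invisible(path)
}
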