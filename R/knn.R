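# Weighted kNN classification and cross-validation engines.
#
# Classifier settings follow the pipeline defaults throughout: k = 10,
# Manhattan (L1) distance, squared-inverse vote weights.  Determinism rules:
# neighbour ties at the k-th position keep the first k in index order; a
# zero-distance neighbour set votes alone by majority; class-score ties
# predict class 1 (AD).

# evaluate expr with a temporary RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# stratified fold assignment (1..nfold per row), shuffled within class
.stratified_folds <- function(y, nfold, seed) {
  foldid <- integer(length(y))
  .with_seed(seed, {
    for (cl in unique(y)) {
      rows <- which(y == cl)
      rows <- sample(rows)
      foldid[rows] <- rep_len(seq_len(nfold), length(rows))
    }
  })
  foldid
}

#' Weighted k-nearest-neighbour classification
#'
#' Manhattan-distance kNN with squared-inverse vote weights: each of the k
#' nearest training rows contributes `1/d^2` to its class score and the
#' larger score wins.  Test rows at distance 0 from any neighbour are
#' decided by majority among the zero-distance neighbours only (the
#' squared-inverse limit).
#'
#' @param train_x,train_y Training matrix (rows = observations) and integer
#'   classes (1 = AD, 2 = control).
#' @param test_x Test matrix with the same columns.
#' @param k Number of neighbours (default 10); must not exceed
#'   `nrow(train_x)`.
#' @return Integer vector of predicted classes, with attribute `score1`
#'   holding the class-1 vote fraction per test row (used for AUC).
#' @examples
#' tr <- matrix(c(0, 1, 4)); knn_classify(tr, c(1, 1, 2), matrix(2.5), k = 3)
#' @export
knn_classify <- function(train_x, train_y, test_x, k = 10L) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  train_y <- as.integer(train_y)
  if (!all(train_y %in% c(1L, 2L))) stop("classes must be coded 1 (AD) / 2 (control)")
  if (k > nrow(train_x)) {
    stop("k = ", k, " exceeds the number of training rows (", nrow(train_x), ")")
  }
  if (nrow(test_x) < 1) stop("need at least one test row")
  if (ncol(test_x) != ncol(train_x)) stop("train and test column counts differ")
  res <- .knn_weighted_cpp(train_x, train_y, test_x, as.integer(k))
  structure(as.integer(res$pred), score1 = as.numeric(res$score1))
}

#' Control object for the feature-selection stage of cross-validation
#'
#' @param method `"inca"` (NCA ranking + iterative prefix search) or
#'   `"none"` (use all features).
#' @param mode `"per-fold"` (default): ranking and INCA are re-run inside
#'   every training fold, so the test subject never influences selection.
#'   `"global"`: selection is run once on the full dataset before
#'   cross-validation; faster and matches a single global selection per
#'   channel, but lets test segments influence the chosen features.
#' @param sizes Candidate prefix sizes (default 50:550).
#' @param k kNN neighbours used by the internal INCA loss (default 10).
#' @return A list of class `selection_control`.
#' @export
selection_control <- function(method = c("inca", "none"),
                              mode = c("per-fold", "global"),
                              sizes = 50:550, k = 10L) {
  structure(
    list(method = match.arg(method), mode = match.arg(mode),
         sizes = as.integer(sizes), k = as.integer(k)),
    class = "selection_control"
  )
}

# run selection on a training set; returns column indices (or NULL for all)
.run_selection <- function(x, y, selection, seed) {
  if (selection$method == "none") return(NULL)
  ranking <- nca_rank(x, y, seed = seed)
  res <- inca_select(x, y, ranking, sizes = selection$sizes,
                     scorer_seed = seed + 1L, k = selection$k)
  res$selected_indices
}

# shared CV engine: folds is a list of test-row index vectors
.cv_predict <- function(x, y, folds, selection, k, seed) {
  n <- nrow(x)
  pred <- integer(n); score1 <- numeric(n)
  sel_global <- if (selection$mode == "global") {
    .run_selection(x, y, selection, seed)
  }
  sizes_used <- integer(0)
  for (f in seq_along(folds)) {
    te <- folds[[f]]; tr <- setdiff(seq_len(n), te)
    sel <- if (selection$mode == "global") sel_global else {
      .run_selection(x[tr, , drop = FALSE], y[tr], selection, seed + f)
    }
    cols <- if (is.null(sel)) seq_len(ncol(x)) else sel
    sizes_used <- c(sizes_used, length(cols))
    keff <- min(k, length(tr))
    p <- knn_classify(x[tr, cols, drop = FALSE], y[tr],
                      x[te, cols, drop = FALSE], k = keff)
    pred[te] <- p
    score1[te] <- attr(p, "score1")
  }
  list(pred = pred, score1 = score1, sizes_used = sizes_used)
}

#' Leave-one-subject-out cross-validation for one channel
#'
#' Every subject in turn forms the test fold; the classifier (and, in
#' `"per-fold"` mode, the whole NCA + INCA selection) is trained on the
#' remaining subjects' segments.  Predictions are assembled in the original
#' segment order.
#'
#' @param dataset A `channel_dataset` (see [build_channel_dataset()]).
#' @param selection A [selection_control()] object.
#' @param k kNN neighbours for the final classifier (default 10, capped at
#'   the training-fold size).
#' @param seed Integer seed driving the selection stage RNG.
#' @return An object of class `loso_result`: list with `predicted`,
#'   `score1`, `truth`, `subjects`, `channel_name`, `fold_subjects` and
#'   `selected_sizes` (features used per fold).
#' @export
loso_cv <- function(dataset, selection = selection_control(), k = 10L,
                    seed = 1L) {
  stopifnot(inherits(dataset, "channel_dataset"))
  subj <- dataset$subjects
  us <- unique(subj)
  if (length(us) < 2) stop("LOSO CV needs at least 2 subjects")
  folds <- lapply(us, function(s) which(subj == s))
  res <- .cv_predict(dataset$x, dataset$y, folds, selection, k, seed)
  structure(
    list(predicted = res$pred, score1 = res$score1, truth = dataset$y,
         subjects = subj, channel_name = dataset$channel_name,
         fold_subjects = us, selected_sizes = res$sizes_used),
    class = "loso_result"
  )
}

#' Stratified k-fold cross-validation for one channel
#'
#' Segment-level stratified folds (no subject grouping); used by the
#' ablation analyses where ten-fold CV replaces LOSO.
#'
#' @inheritParams loso_cv
#' @param nfold Number of folds (default 10).
#' @return A `loso_result` (with `fold_subjects = NULL`).
#' @export
kfold_cv <- function(dataset, selection = selection_control(), k = 10L,
                     nfold = 10L, seed = 1L) {
  stopifnot(inherits(dataset, "channel_dataset"))
  nfold <- min(nfold, nrow(dataset$x))
  foldid <- .stratified_folds(dataset$y, nfold, seed)
  folds <- lapply(seq_len(nfold), function(f) which(foldid == f))
  folds <- folds[lengths(folds) > 0]
  res <- .cv_predict(dataset$x, dataset$y, folds, selection, k, seed)
  structure(
    list(predicted = res$pred, score1 = res$score1, truth = dataset$y,
         subjects = dataset$subjects, channel_name = dataset$channel_name,
         fold_subjects = NULL, selected_sizes = res$sizes_used),
    class = "loso_result"
  )
}
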