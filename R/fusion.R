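# Post-processing / information fusion: iterative majority voting over
# accuracy-sorted channel predictions, performance metrics, greedy selection
# of the single best candidate, and region-wise accuracy summaries.
#
# Note: the voting order, and the greedy winner, are chosen using the truth
# labels, i.e. fusion is a label-dependent, self-organized model-selection
# step (reported as such), not a blind ensemble.

.accuracy <- function(pred, truth) mean(pred == truth)

#' Iterative majority voting over channel predictions
#'
#' Sorts the channel prediction vectors by accuracy against the truth
#' (descending, accuracy ties toward the lower channel index) and, for every
#' n from 3 up to the number of channels, outputs the element-wise mode of
#' the top-n vectors (mode ties toward the lower class id).  With 20
#' channels this yields 18 voted vectors.
#'
#' @param channel_results List of integer prediction vectors (classes 1/2),
#'   one per channel, all the same length.
#' @param truth Integer truth labels of that length.
#' @return List of voted prediction vectors named `n3`, `n4`, ...; each has
#'   attribute `n_channels`.
#' @export
imv_vote <- function(channel_results, truth) {
  len <- lengths(channel_results)
  if (length(unique(len)) != 1 || len[1] != length(truth)) {
    stop("all prediction vectors and truth must have the same length")
  }
  nc <- length(channel_results)
  if (nc < 3) stop("IMV needs at least 3 channel results")
  acc <- vapply(channel_results, .accuracy, numeric(1), truth = truth)
  ord <- order(-acc, seq_len(nc)) # ties -> lower channel index
  pred_mat <- do.call(cbind, channel_results[ord])
  voted <- lapply(3:nc, function(n) {
    top <- pred_mat[, seq_len(n), drop = FALSE]
    votes1 <- rowSums(top == 1L)
    v <- ifelse(votes1 * 2 >= n, 1L, 2L) # mode tie -> class 1
    structure(as.integer(v), n_channels = n)
  })
  names(voted) <- paste0("n", 3:nc)
  voted
}

#' Classification performance metrics
#'
#' Confusion counts with class 1 (AD) as the positive class, plus accuracy,
#' geometric mean `sqrt(sensitivity * specificity)`, precision, recall, F1,
#' Cohen's kappa and (when per-segment class-1 scores are supplied) the
#' rank-based AUC, all expressed as percentages.
#'
#' @param predicted,truth Integer vectors of classes in `{1, 2}`.
#' @param scores Optional numeric class-1 scores (e.g. the kNN
#'   squared-inverse class-1 vote fraction) for AUC.
#' @return An object of class `ghpat_metrics`: list with `TP`, `TN`, `FP`,
#'   `FN` and the percentage metrics (`auc = NA` without scores).
#' @examples
#' compute_metrics(c(1, 1, 2, 2), c(1, 2, 2, 2))$accuracy  # 75
#' @export
compute_metrics <- function(predicted, truth, scores = NULL) {
  if (length(predicted) == 0) stop("empty input")
  if (length(predicted) != length(truth)) stop("length mismatch")
  if (!all(c(predicted, truth) %in% c(1L, 2L))) {
    stop("classes must be coded 1 (AD) / 2 (control)")
  }
  tp <- sum(predicted == 1 & truth == 1)
  tn <- sum(predicted == 2 & truth == 2)
  fp <- sum(predicted == 1 & truth == 2)
  fn <- sum(predicted == 2 & truth == 1)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  prec <- tp / (tp + fp)
  acc <- (tp + tn) / length(truth)
  f1 <- 2 * prec * sens / (prec + sens)
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / length(truth)^2
  kappa <- (acc - pe) / (1 - pe)
  auc <- NA_real_
  if (!is.null(scores)) {
    s1 <- scores[truth == 1]; s2 <- scores[truth == 2]
    if (length(s1) > 0 && length(s2) > 0) {
      r <- rank(c(s1, s2))
      auc <- (sum(r[seq_along(s1)]) - length(s1) * (length(s1) + 1) / 2) /
        (length(s1) * length(s2))
    }
  }
  structure(
    list(TP = tp, TN = tn, FP = fp, FN = fn,
         accuracy = 100 * acc,
         geometric_mean = 100 * sqrt(sens * spec),
         precision = 100 * prec,
         recall = 100 * sens,
         f1 = 100 * f1,
         cohens_kappa = 100 * kappa,
         auc = 100 * auc),
    class = "ghpat_metrics"
  )
}

#' @export
print.ghpat_metrics <- function(x, ...) {
  cat(sprintf(
    "TP %d  TN %d  FP %d  FN %d\naccuracy %.2f%%  gm %.2f%%  precision %.2f%%  recall %.2f%%\nF1 %.2f%%  kappa %.2f%%  AUC %s\n",
    x$TP, x$TN, x$FP, x$FN, x$accuracy, x$geometric_mean, x$precision,
    x$recall, x$f1, x$cohens_kappa,
    if (is.na(x$auc)) "NA" else sprintf("%.2f%%", x$auc)
  ))
  invisible(x)
}

#' Greedy selection of the most accurate candidate result
#'
#' Pools the channel-wise prediction vectors with the IMV-voted vectors
#' (20 + 18 = 38 candidates for a full montage) and picks the single most
#' accurate one; accuracy ties go to the lower candidate index (channels
#' before voted results).
#'
#' @param channel_results List of channel prediction vectors.
#' @param voted_results List of voted prediction vectors from [imv_vote()].
#' @param truth Integer truth labels.
#' @return An object of class `fusion_report`: list with `accuracies` (all
#'   candidates, channels first), `winner_index`, `winner_name`, `ultimate`
#'   (the winning prediction vector), `n_channels`, `n_voted`.
#' @export
greedy_best <- function(channel_results, voted_results, truth) {
  candidates <- c(channel_results, voted_results)
  acc <- vapply(candidates, .accuracy, numeric(1), truth = truth)
  ind <- order(-acc, seq_along(acc))[1]
  nm <- names(candidates)
  if (is.null(nm)) nm <- paste0("cand", seq_along(candidates))
  structure(
    list(accuracies = stats::setNames(100 * acc, nm),
         winner_index = ind,
         winner_name = nm[ind],
         ultimate = candidates[[ind]],
         n_channels = length(channel_results),
         n_voted = length(voted_results)),
    class = "fusion_report"
  )
}

# fixed electrode groups for region summaries
.region_groups <- list(
  parietal = c("P3", "P4"),
  central = c("C3", "C4", "Cz"),
  occipital = c("O1", "O2"),
  temporal = c("T3", "T4", "T5", "T6"),
  frontal = c("F3", "F4", "F7", "F8", "Fz"),
  prefrontal = c("Fp1", "Fp2"),
  anterior = c("A1", "A2")
)

#' Region-wise mean channel accuracies
#'
#' Averages channel accuracies over fixed scalp regions: parietal (P3, P4),
#' central (C3, C4, Cz), occipital (O1, O2), temporal (T3, T4, T5, T6),
#' frontal (F3, F4, F7, F8, Fz), prefrontal (Fp1, Fp2) and anterior
#' (A1, A2).  Results are rounded to 2 decimals for reporting.
#'
#' @param channel_accuracies Named numeric vector (channel name ->
#'   accuracy), covering all montage channels.
#' @return Named numeric vector of region means.
#' @examples
#' region_average(setNames(rep(80, 20), ghpat_montage()))
#' @export
region_average <- function(channel_accuracies) {
  vapply(.region_groups, function(chs) {
    missing <- setdiff(chs, names(channel_accuracies))
    if (length(missing) > 0) {
      stop("missing channel accuracy for: ", paste(missing, collapse = ", "))
    }
    round(mean(channel_accuracies[chs]), 2)
  }, numeric(1))
}
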