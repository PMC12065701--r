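# Record readers and the full self-organized pipeline.

#' Read a multichannel EEG record (EDF or delimited text)
#'
#' Delimited files (`.csv`, `.tsv`, `.txt`) are samples x channels with a
#' header row naming the channels; `.edf` files carry their own labels and
#' sampling rate.  Channels are re-ordered to the requested montage order.
#'
#' @param path Input file.
#' @param montage Channel-name vector defining the output order (default the
#'   intersection of the file's channels with [ghpat_montage()], in montage
#'   order).
#' @param fs Sampling rate for delimited files (ignored for EDF, which
#'   stores it).
#' @param strict If `TRUE`, error when a montage channel is missing;
#'   otherwise missing channels are dropped with a message.
#' @return List with `record` (channels x samples matrix in montage order),
#'   `fs` and `missing` (channels requested but absent).
#' @export
read_eeg <- function(path, montage = NULL, fs = NULL, strict = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "edf") {
    r <- read_edf(path)
    record <- r$record
    fs <- r$fs
  } else if (ext %in% c("csv", "tsv", "txt")) {
    dt <- data.table::fread(path)
    record <- t(as.matrix(dt))
    if (is.null(fs)) stop("fs must be supplied for delimited records")
  } else {
    stop("unknown record format: .", ext, " (expected .edf/.csv/.tsv/.txt)")
  }
  if (is.null(montage)) montage <- intersect(ghpat_montage(), rownames(record))
  missing <- setdiff(montage, rownames(record))
  if (length(missing) > 0) {
    if (strict) stop("missing required channels: ", paste(missing, collapse = ", "))
    message("dropping missing channels: ", paste(missing, collapse = ", "))
    montage <- setdiff(montage, missing)
  }
  list(record = record[montage, , drop = FALSE], fs = fs, missing = missing)
}

#' Pipeline configuration
#'
#' Defaults reproduce the method's reference architecture: 7-level sym4
#' wavelet cascade, GHPat + 14 statistical moments per band (270 features,
#' 2160 per segment), INCA over prefix sizes 50-550 with a kNN loss, weighted
#' kNN (k = 10, Manhattan, squared-inverse) under LOSO CV, IMV over n = 3-20
#' and greedy selection among all 38 candidates.
#'
#' @param fs Sampling rate in Hz (default 500).
#' @param window_s Segment length in seconds (default 15).
#' @param levels Wavelet levels (default 7).
#' @param wavelet Mother wavelet (only `"sym4"`).
#' @param mu_mode GHPat subgraph-mean mode (`"nodeset"` or `"literal"`).
#' @param tsallis_q,sure_eps Entropy parameters.
#' @param k kNN neighbours (default 10).
#' @param inca_sizes INCA candidate prefix sizes (default 50:550).
#' @param selection_mode `"per-fold"` (leakage-free, default) or `"global"`
#'   (one selection per channel before CV).
#' @param ablation_case 1 = GHPat features only, 2 = statistical moments
#'   only, 3 = GHPat + moments, 4 = classic 1-D LBP baseline, 5 = the full
#'   model (GHPat + moments with INCA; default).  Cases 1-4 skip nothing
#'   else: selection, classification and fusion still run on the variant
#'   features.
#' @param cv `"loso"` (default) or `"kfold10"`.
#' @param seed Integer seed for all stochastic stages.
#' @return A validated list of class `ghpat_config`.
#' @export
ghpat_config <- function(fs = 500, window_s = 15, levels = 7L,
                         wavelet = "sym4",
                         mu_mode = c("nodeset", "literal"),
                         tsallis_q = 2, sure_eps = 3,
                         k = 10L, inca_sizes = 50:550,
                         selection_mode = c("per-fold", "global"),
                         ablation_case = 5L,
                         cv = c("loso", "kfold10"),
                         seed = 1L) {
  mu_mode <- match.arg(mu_mode)
  selection_mode <- match.arg(selection_mode)
  cv <- match.arg(cv)
  if (!identical(wavelet, "sym4")) stop("only the sym4 wavelet is supported")
  ablation_case <- as.integer(ablation_case)
  if (!ablation_case %in% 1:5) stop("ablation_case must be in 1..5")
  structure(
    list(fs = fs, window_s = window_s, levels = as.integer(levels),
         wavelet = wavelet, mu_mode = mu_mode,
         tsallis_q = tsallis_q, sure_eps = sure_eps,
         k = as.integer(k), inca_sizes = as.integer(inca_sizes),
         selection_mode = selection_mode, ablation_case = ablation_case,
         cv = cv, seed = as.integer(seed)),
    class = "ghpat_config"
  )
}

.ablation_extractor <- c("ghpat", "stats", "ghpat_stats", "lbp", "ghpat_stats")

#' Run the full self-organized classification pipeline
#'
#' Segments every record, extracts per-segment features for each channel
#' (per the ablation case), runs INCA-selected weighted-kNN classification
#' under the configured cross-validation, fuses the channel results by
#' iterative majority voting, and greedily selects the single most accurate
#' of the pooled candidates.
#'
#' @param records List of channels x samples matrices (channel names as row
#'   names), one per subject.
#' @param labels Integer class per record (1 = AD, 2 = control).
#' @param subjects Subject identifier per record.
#' @param config A [ghpat_config()].
#' @param channels Channels to model (default: all channels common to every
#'   record, in montage order).
#' @param verbose Print per-channel progress.
#' @return An object of class `ghpat_fit`; see [summary.ghpat_fit()].
#' @export
ghpat_pipeline <- function(records, labels, subjects, config = ghpat_config(),
                           channels = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "ghpat_config"))
  if (is.null(channels)) {
    common <- Reduce(intersect, lapply(records, rownames))
    channels <- intersect(ghpat_montage(), common)
    if (length(channels) == 0) channels <- common
  }
  if (length(channels) < 1) stop("no channels to model")
  extractor <- .ablation_extractor[config$ablation_case]
  selection <- selection_control(
    method = "inca", mode = config$selection_mode,
    sizes = config$inca_sizes, k = config$k
  )
  channel_results <- list()
  channel_scores <- list()
  selected_sizes <- list()
  truth <- NULL
  for (ch in channels) {
    if (verbose) message("channel ", ch)
    ds <- build_channel_dataset(
      records, labels, subjects, ch,
      fs = config$fs, window_s = config$window_s,
      extractor = extractor, levels = config$levels,
      mu_mode = config$mu_mode, tsallis_q = config$tsallis_q,
      sure_eps = config$sure_eps
    )
    res <- if (config$cv == "loso") {
      loso_cv(ds, selection, k = config$k, seed = config$seed)
    } else {
      kfold_cv(ds, selection, k = config$k, nfold = 10L, seed = config$seed)
    }
    truth <- res$truth
    channel_results[[ch]] <- res$predicted
    channel_scores[[ch]] <- res$score1
    selected_sizes[[ch]] <- res$selected_sizes
  }
  voted <- if (length(channel_results) >= 3) {
    imv_vote(channel_results, truth)
  } else {
    list()
  }
  fusion <- greedy_best(channel_results, voted, truth)
  channel_acc <- fusion$accuracies[seq_along(channel_results)]
  regions <- if (all(ghpat_montage() %in% names(channel_acc))) {
    region_average(channel_acc)
  }
  ult_scores <- if (fusion$winner_index <= length(channel_results)) {
    channel_scores[[fusion$winner_index]]
  }
  metrics <- compute_metrics(fusion$ultimate, truth, scores = ult_scores)
  structure(
    list(config = config, channels = channels, truth = truth,
         subjects_per_segment = rep(subjects,
           times = vapply(records, function(r) ncol(r) %/%
                            as.integer(round(config$fs * config$window_s)),
                          integer(1))),
         channel_results = channel_results,
         channel_scores = channel_scores,
         selected_sizes = selected_sizes,
         voted_results = voted, fusion = fusion,
         channel_accuracies = channel_acc,
         region_accuracies = regions,
         metrics = metrics),
    class = "ghpat_fit"
  )
}

#' @export
print.ghpat_fit <- function(x, ...) {
  cat("GHPat self-organized classification fit\n")
  cat(sprintf("  channels: %d   segments: %d   CV: %s   ablation case: %d\n",
              length(x$channels), length(x$truth), x$config$cv,
              x$config$ablation_case))
  cat(sprintf("  candidates: %d channel-wise + %d voted = %d\n",
              x$fusion$n_channels, x$fusion$n_voted,
              x$fusion$n_channels + x$fusion$n_voted))
  cat(sprintf("  ultimate result: %s  accuracy %.2f%%  gm %.2f%%\n",
              x$fusion$winner_name, x$metrics$accuracy,
              x$metrics$geometric_mean))
  invisible(x)
}

#' Summarize a pipeline fit
#'
#' @param object A `ghpat_fit`.
#' @param ... Unused.
#' @return `object`, invisibly, after printing channel-wise, voted, region
#'   and overall metrics.
#' @export
summary.ghpat_fit <- function(object, ...) {
  print(object)
  cat("\nchannel-wise accuracies (%):\n")
  print(round(object$channel_accuracies, 2))
  if (length(object$voted_results) > 0) {
    va <- object$fusion$accuracies[-seq_along(object$channel_results)]
    cat("\nvoted accuracies (%):\n")
    print(round(va, 2))
  }
  if (!is.null(object$region_accuracies)) {
    cat("\nregion means (%):\n")
    print(object$region_accuracies)
  }
  cat("\nultimate result metrics:\n")
  print(object$metrics)
  invisible(object)
}

#' Plot channel-wise accuracies of a fit
#'
#' Bar plot of per-channel accuracy with the fused ultimate accuracy as a
#' reference line.
#'
#' @param x A `ghpat_fit`.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly `x`.
#' @export
plot.ghpat_fit <- function(x, ...) {
  graphics::barplot(x$channel_accuracies, las = 2,
                    ylab = "LOSO accuracy (%)", ...)
  graphics::abline(h = x$metrics$accuracy, lty = 2)
  invisible(x)
}

#' Run the pipeline from a cohort directory and write artifacts
#'
#' File-level wrapper used by the command-line interface: reads a cohort
#' (see [write_cohort()]), runs [ghpat_pipeline()], and writes per-channel
#' prediction CSVs, a fusion report JSON and (for a full montage) a region
#' summary CSV.
#'
#' @param input_dir Cohort directory containing `manifest.csv`.
#' @param out_dir Output directory.
#' @param config A [ghpat_config()].
#' @param verbose Print progress.
#' @return The `ghpat_fit`, invisibly.
#' @export
run_pipeline <- function(input_dir, out_dir, config = ghpat_config(),
                         verbose = FALSE) {
  cohort <- read_cohort(input_dir)
  fit <- ghpat_pipeline(cohort$records, cohort$labels, cohort$subject_ids,
                        config, verbose = verbose)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in names(fit$channel_results)) {
    data.table::fwrite(
      data.table::data.table(
        segment = seq_along(fit$truth),
        subject = fit$subjects_per_segment,
        truth = fit$truth,
        prediction = fit$channel_results[[ch]],
        score1 = fit$channel_scores[[ch]]
      ),
      file.path(out_dir, paste0("predictions_", ch, ".csv"))
    )
  }
  report <- list(
    config = unclass(fit$config),
    accuracies = as.list(fit$fusion$accuracies),
    winner = fit$fusion$winner_name,
    metrics = unclass(fit$metrics)
  )
  jsonlite::write_json(report, file.path(out_dir, "fusion_report.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(fit$region_accuracies)) {
    data.table::fwrite(
      data.table::data.table(region = names(fit$region_accuracies),
                             mean_accuracy = fit$region_accuracies),
      file.path(out_dir, "region_summary.csv")
    )
  }
  invisible(fit)
}
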