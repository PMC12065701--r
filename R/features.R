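# Multilevel feature assembly: segmentation of multichannel records and the
# fusion of GHPat textural + statistical features over the raw segment and
# its 7 low-pass wavelet bands.
#
# Final per-segment layout (default extractor): 8 blocks of 270 features
# ([256 textural | 14 statistical]) in band order [raw | low1 | ... | low7],
# i.e. 2160 features in total.

#' The 20-channel EEG montage, in channel order
#'
#' Standard 10-20 electrode names in the fixed order used throughout the
#' pipeline: Fp1, Fp2, F3, F4, C3, C4, P3, P4, O1, O2, F7, F8, T3, T4, T5,
#' T6, A1, A2, Fz, Cz.
#' @return Character vector of length 20.
#' @export
ghpat_montage <- function() {
  c(
    "Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
    "F7", "F8", "T3", "T4", "T5", "T6", "A1", "A2", "Fz", "Cz"
  )
}

#' Split a multichannel record into non-overlapping segments
#'
#' Divides each channel into consecutive windows of `fs * window_s` samples;
#' a trailing partial window is dropped.
#'
#' @param record Numeric matrix, channels x samples, with channel names as
#'   row names.
#' @param fs Sampling rate in Hz.
#' @param window_s Window length in seconds (default 15).
#' @return Named list (one element per channel) of `n_segments x window`
#'   matrices, one row per segment.
#' @examples
#' r <- matrix(rnorm(2 * 20000), 2, dimnames = list(c("C3", "C4"), NULL))
#' lengths(lapply(segment_record(r, fs = 500), nrow))
#' @export
segment_record <- function(record, fs, window_s = 15) {
  if (!is.matrix(record) || !is.numeric(record)) {
    stop("record must be a numeric channels x samples matrix")
  }
  if (fs <= 0) stop("fs must be positive")
  win <- as.integer(round(fs * window_s))
  n <- ncol(record)
  n_seg <- n %/% win
  if (n_seg < 1) {
    stop("record has ", n, " samples; shorter than one ", win, "-sample window")
  }
  ch_names <- rownames(record)
  if (is.null(ch_names)) ch_names <- paste0("ch", seq_len(nrow(record)))
  out <- lapply(seq_len(nrow(record)), function(ci) {
    matrix(record[ci, seq_len(n_seg * win)], nrow = n_seg, ncol = win, byrow = TRUE)
  })
  names(out) <- ch_names
  out
}

# per-band extractor widths, by ablation variant
.band_extractors <- list(
  ghpat_stats = list(width = 270L,
                     fn = function(x, mu_mode, tsallis_q, sure_eps) {
                       c(ghpat_transform(x, mu_mode),
                         statistical_features(x, tsallis_q, sure_eps))
                     }),
  ghpat = list(width = 256L,
               fn = function(x, mu_mode, ...) ghpat_transform(x, mu_mode)),
  stats = list(width = 14L,
               fn = function(x, mu_mode, tsallis_q, sure_eps) {
                 statistical_features(x, tsallis_q, sure_eps)
               }),
  lbp = list(width = 256L,
             fn = function(x, ...) lbp1d_baseline(x))
)

#' Final feature vector of one segment
#'
#' Decomposes the segment with [mdwt_lowpass()] and concatenates one
#' per-band feature block for the raw segment and each of the `levels`
#' low-pass bands, in that order.  With the default extractor each block is
#' 270-wide (256 GHPat counts then 14 statistical moments), giving a final
#' vector of length 270 x (levels + 1) = 2160.
#'
#' @param segment Numeric vector (7500 samples for a 15-s window at 500 Hz).
#' @param extractor Per-band feature variant: `"ghpat_stats"` (default, the
#'   full method), `"ghpat"`, `"stats"` or `"lbp"` (classic 1-D local binary
#'   pattern, ablation baseline).
#' @param levels Wavelet cascade depth (default 7).
#' @param mu_mode Subgraph-mean mode, see [select_subgraph()].
#' @param tsallis_q,sure_eps Entropy parameters, see
#'   [statistical_features()].
#' @return Named numeric vector of length `width * (levels + 1)`.
#' @export
extract_segment_features <- function(segment,
                                     extractor = c("ghpat_stats", "ghpat",
                                                   "stats", "lbp"),
                                     levels = 7L,
                                     mu_mode = c("nodeset", "literal"),
                                     tsallis_q = 2, sure_eps = 3) {
  extractor <- match.arg(extractor)
  mu_mode <- match.arg(mu_mode)
  ex <- .band_extractors[[extractor]]
  bands <- mdwt_lowpass(segment, levels = levels)
  inputs <- c(list(as.numeric(segment)), bands$lowpass)
  names(inputs) <- c("raw", paste0("low", seq_len(levels)))
  out <- unlist(lapply(names(inputs), function(nm) {
    v <- ex$fn(inputs[[nm]], mu_mode = mu_mode,
               tsallis_q = tsallis_q, sure_eps = sure_eps)
    names(v) <- paste0(nm, ".", if (is.null(names(v))) seq_along(v) else names(v))
    v
  }))
  stopifnot(length(out) == ex$width * (levels + 1L))
  out
}

#' Per-channel labeled feature dataset
#'
#' Segments every record, extracts one final feature vector per segment for
#' the requested channel, and assembles the segments x features matrix with
#' its class labels and subject identifiers.
#'
#' @param records List of channels x samples matrices (one per subject or
#'   recording), each with channel names as row names.
#' @param labels Integer class per record (1 = AD, 2 = control).
#' @param subjects Subject identifier per record.
#' @param channel Channel name to extract.
#' @param fs Sampling rate in Hz (default 500).
#' @param window_s Segment length in seconds (default 15).
#' @inheritParams extract_segment_features
#' @return An object of class `channel_dataset`: list with `x` (nos x d
#'   matrix), `y` (class per segment), `subjects` (subject per segment) and
#'   `channel_name`.
#' @export
build_channel_dataset <- function(records, labels, subjects, channel,
                                  fs = 500, window_s = 15,
                                  extractor = "ghpat_stats", levels = 7L,
                                  mu_mode = "nodeset",
                                  tsallis_q = 2, sure_eps = 3) {
  stopifnot(length(records) == length(labels),
            length(records) == length(subjects))
  rows <- list(); y <- integer(0); subj <- character(0)
  for (i in seq_along(records)) {
    segs <- segment_record(records[[i]], fs = fs, window_s = window_s)
    if (!channel %in% names(segs)) {
      stop("record ", i, " is missing channel ", channel)
    }
    sm <- segs[[channel]]
    for (s in seq_len(nrow(sm))) {
      rows[[length(rows) + 1L]] <- extract_segment_features(
        sm[s, ], extractor = extractor, levels = levels, mu_mode = mu_mode,
        tsallis_q = tsallis_q, sure_eps = sure_eps
      )
      y <- c(y, as.integer(labels[i]))
      subj <- c(subj, as.character(subjects[i]))
    }
  }
  x <- do.call(rbind, rows)
  new_channel_dataset(x, y, subj, channel)
}

#' Construct a channel dataset from components
#'
#' @param x Numeric nos x d feature matrix.
#' @param y Integer class per row (1 = AD, 2 = control).
#' @param subjects Subject identifier per row.
#' @param channel_name Channel name.
#' @return `channel_dataset` object.
#' @export
new_channel_dataset <- function(x, y, subjects, channel_name) {
  stopifnot(nrow(x) == length(y), nrow(x) == length(subjects))
  mixed <- tapply(y, subjects, function(v) length(unique(v)) > 1L)
  if (any(mixed)) {
    stop("subjects with mixed labels: ",
         paste(names(mixed)[mixed], collapse = ", "))
  }
  structure(
    list(x = x, y = as.integer(y), subjects = as.character(subjects),
         channel_name = channel_name),
    class = "channel_dataset"
  )
}

#' Write / read a per-channel feature table as delimited text
#'
#' One row per segment: the feature columns followed by `label`, `subject`
#' and `channel`.
#'
#' @param dataset A `channel_dataset`.
#' @param path Output (input) file path, tab-separated.
#' @return `write_feature_table` invisibly returns `path`;
#'   `read_feature_table` returns the `channel_dataset`.
#' @export
write_feature_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "channel_dataset"))
  dt <- data.table::as.data.table(dataset$x)
  dt$label <- dataset$y
  dt$subject <- dataset$subjects
  dt$channel <- dataset$channel_name
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  meta <- c("label", "subject", "channel")
  if (!all(meta %in% names(dt))) stop("not a feature table: ", path)
  x <- as.matrix(dt[, setdiff(names(dt), meta), with = FALSE])
  new_channel_dataset(x, dt$label, dt$subject, unique(dt$channel)[1])
}
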