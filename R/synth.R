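# Seeded generator of EEG-like two-class cohorts.
#
# Each segment is a sum of five band-limited noise components (delta
# 0.5-4 Hz, theta 4-8, alpha 8-13, beta 13-30, gamma 30-100) plus white
# noise.  Class 1 ("AD") raises delta/theta/gamma power and lowers
# alpha/beta power by a configurable multiplicative effect, emulating the
# band-power shifts reported for Alzheimer's EEG; a log-normal per-subject
# per-band gain adds between-subject structure.  Not biophysically realistic
# EEG: no dipole geometry, artifacts, or channel correlation structure.

.synth_bands <- list(
  delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
  beta = c(13, 30), gamma = c(30, 100)
)
# 1/f-flavoured base amplitudes
.synth_base_gain <- c(delta = 1.0, theta = 0.8, alpha = 0.6,
                      beta = 0.4, gamma = 0.2)
.synth_ad_up <- c("delta", "theta", "gamma") # raised in class 1

#' Configuration of a synthetic EEG cohort
#'
#' @param n_subjects_per_class Subjects per class (default 10).
#' @param segments_per_subject 15-s segments per subject (default 4).
#' @param fs Sampling rate in Hz (default 500).
#' @param segment_s Segment length in seconds (default 15).
#' @param n_channels Number of channels, named from [ghpat_montage()]
#'   (default 20).
#' @param band_gain_effect Relative class effect `e`: class-1 subjects get
#'   delta/theta/gamma amplitudes multiplied by `1 + e` and alpha/beta
#'   amplitudes divided by `1 + e`.  `e = 0` gives a class-blind (null)
#'   generator; the default `e = 1` is a strong (x2) shift.
#' @param subject_sd Standard deviation of the per-subject log-normal band
#'   gain (default 0.2).
#' @param noise_sd Additive white-noise scale (default 0.5).
#' @param seed Integer seed (default 1).
#' @return A validated list of class `synthetic_cohort_config`.
#' @export
synthetic_cohort_config <- function(n_subjects_per_class = 10L,
                                    segments_per_subject = 4L,
                                    fs = 500, segment_s = 15,
                                    n_channels = 20L,
                                    band_gain_effect = 1,
                                    subject_sd = 0.2,
                                    noise_sd = 0.5,
                                    seed = 1L) {
  cfg <- list(
    n_subjects_per_class = as.integer(n_subjects_per_class),
    segments_per_subject = as.integer(segments_per_subject),
    fs = fs, segment_s = segment_s,
    n_channels = as.integer(n_channels),
    band_gain_effect = band_gain_effect,
    subject_sd = subject_sd, noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  with(cfg, {
    if (n_subjects_per_class < 1 || segments_per_subject < 1 || n_channels < 1) {
      stop("all counts must be positive")
    }
    if (fs <= 0 || segment_s <= 0) stop("fs and segment_s must be positive")
    if (abs(fs * segment_s - round(fs * segment_s)) > 1e-9) {
      stop("fs * segment_s must be an integer number of samples")
    }
    if (band_gain_effect < 0) stop("band_gain_effect must be >= 0")
    if (n_channels > 20) stop("at most the 20 montage channels are supported")
  })
  structure(cfg, class = "synthetic_cohort_config")
}

# unit-variance band-limited noise (4th-order Butterworth bandpass)
.band_noise <- function(n, band, fs) {
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, stats::rnorm(n))
  y / stats::sd(y)
}

#' Generate a synthetic two-class EEG cohort
#'
#' Produces one continuous multichannel record per subject
#' (`segments_per_subject` windows long), deterministic under the config
#' seed.  Class labels are 1 (the band-shifted "AD-like" class) and 2
#' (control).
#'
#' @param config A [synthetic_cohort_config()].
#' @return List of class `synthetic_cohort` with `records` (named list of
#'   channels x samples matrices, channel names as row names), `labels`
#'   (integer per record), `subject_ids`, and `config`.
#' @examples
#' cohort <- generate_cohort(synthetic_cohort_config(
#'   n_subjects_per_class = 2, segments_per_subject = 1, n_channels = 2))
#' dim(cohort$records[[1]])
#' @export
generate_cohort <- function(config = synthetic_cohort_config()) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  win <- as.integer(round(config$fs * config$segment_s))
  nsamp <- win * config$segments_per_subject
  channels <- ghpat_montage()[seq_len(config$n_channels)]
  mult <- 1 + config$band_gain_effect
  band_names <- names(.synth_bands)
  ids <- c(sprintf("AD%02d", seq_len(config$n_subjects_per_class)),
           sprintf("CT%02d", seq_len(config$n_subjects_per_class)))
  labels <- rep(1:2, each = config$n_subjects_per_class)
  records <- .with_seed(config$seed, {
    lapply(seq_along(ids), function(si) {
      class_mult <- if (labels[si] == 1L) {
        ifelse(band_names %in% .synth_ad_up, mult, 1 / mult)
      } else {
        rep(1, length(band_names))
      }
      subj_gain <- exp(stats::rnorm(length(band_names), 0, config$subject_sd))
      amps <- .synth_base_gain * class_mult * subj_gain
      rec <- matrix(0, length(channels), nsamp,
                    dimnames = list(channels, NULL))
      for (ci in seq_along(channels)) {
        x <- stats::rnorm(nsamp, sd = config$noise_sd)
        for (bi in seq_along(band_names)) {
          x <- x + amps[bi] * .band_noise(nsamp, .synth_bands[[bi]], config$fs)
        }
        rec[ci, ] <- x
      }
      rec
    })
  })
  names(records) <- ids
  structure(
    list(records = records, labels = labels, subject_ids = ids,
         config = config),
    class = "synthetic_cohort"
  )
}

#' Write / read a cohort as files plus a manifest
#'
#' Writes one record file per subject (`<id>.csv`, samples x channels with a
#' header row, or `<id>.edf`) and a `manifest.csv` with columns `subject`,
#' `label`, `file`, `fs` — the exact input surface of the main pipeline.
#'
#' @param cohort A `synthetic_cohort` (or compatible list).
#' @param dir Output directory (created if needed).
#' @param format `"csv"` (default) or `"edf"`.
#' @return `write_cohort` invisibly returns `dir`; `read_cohort` returns a
#'   list with `records`, `labels`, `subject_ids`.
#' @export
write_cohort <- function(cohort, dir, format = c("csv", "edf")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fs <- cohort$config$fs
  files <- character(length(cohort$records))
  for (i in seq_along(cohort$records)) {
    id <- cohort$subject_ids[i]
    rec <- cohort$records[[i]]
    if (format == "csv") {
      files[i] <- paste0(id, ".csv")
      data.table::fwrite(data.table::as.data.table(t(rec)),
                         file.path(dir, files[i]))
    } else {
      files[i] <- paste0(id, ".edf")
      write_edf(rec, fs, file.path(dir, files[i]))
    }
  }
  data.table::fwrite(
    data.table::data.table(subject = cohort$subject_ids,
                           label = cohort$labels, file = files, fs = fs),
    file.path(dir, "manifest.csv")
  )
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) stop("no manifest.csv in ", dir)
  man <- data.table::fread(mpath)
  records <- lapply(seq_len(nrow(man)), function(i) {
    read_eeg(file.path(dir, man$file[i]), fs = man$fs[i])$record
  })
  names(records) <- man$subject
  list(records = records, labels = as.integer(man$label),
       subject_ids = as.character(man$subject), fs = man$fs[1])
}
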