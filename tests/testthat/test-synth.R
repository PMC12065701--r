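# Synthetic cohort generator.

test_that("config validation rejects impossible cohorts", {
  expect_error(synthetic_cohort_config(n_subjects_per_class = 0), "positive")
  expect_error(synthetic_cohort_config(fs = 100, segment_s = 0.155),
               "integer number of samples")
  expect_error(synthetic_cohort_config(band_gain_effect = -0.5), ">= 0")
  expect_error(synthetic_cohort_config(n_channels = 25), "20")
})

test_that("cohorts are bit-identical under a fixed seed", {
  cfg <- synthetic_cohort_config(n_subjects_per_class = 2,
                                 segments_per_subject = 1, n_channels = 2,
                                 seed = 77)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$records, b$records)
  expect_equal(a$labels, rep(1:2, each = 2))
  expect_equal(dim(a$records[[1]]), c(2, 7500))
  expect_equal(rownames(a$records[[1]]), c("Fp1", "Fp2"))
  # a different seed changes the data
  cfg2 <- synthetic_cohort_config(n_subjects_per_class = 2,
                                  segments_per_subject = 1, n_channels = 2,
                                  seed = 78)
  expect_false(identical(a$records, generate_cohort(cfg2)$records))
})

test_that("class 1 shifts band power in the advertised directions", {
  coh <- generate_cohort(synthetic_cohort_config(
    n_subjects_per_class = 6, segments_per_subject = 2, n_channels = 2,
    band_gain_effect = 1, subject_sd = 0.1, seed = 55
  ))
  fs <- 500
  seg_power <- function(rec, lo, hi) {
    segs <- segment_record(rec, fs)
    mean(apply(segs[[1]], 1, band_power, fs = fs, lo = lo, hi = hi))
  }
  p <- function(lo, hi) {
    sapply(seq_along(coh$records), function(i) seg_power(coh$records[[i]], lo, hi))
  }
  ad <- coh$labels == 1
  # delta/theta up, alpha/beta down for the AD-like class (n >= 20 segments)
  expect_gt(mean(p(0.5, 8)[ad]), mean(p(0.5, 8)[!ad]))
  expect_lt(mean(p(8, 30)[ad]), mean(p(8, 30)[!ad]))
  expect_gt(mean(p(30, 100)[ad]), mean(p(30, 100)[!ad]))
})

test_that("within-subject band-power correlation exceeds between-subject", {
  coh <- generate_cohort(synthetic_cohort_config(
    n_subjects_per_class = 5, segments_per_subject = 3, n_channels = 1,
    band_gain_effect = 0, subject_sd = 0.5, noise_sd = 0.1, seed = 66
  ))
  fs <- 500
  bands <- list(c(0.5, 4), c(4, 8), c(8, 13), c(13, 30), c(30, 100))
  feats <- list(); subj <- character(0)
  for (i in seq_along(coh$records)) {
    segs <- segment_record(coh$records[[i]], fs)[[1]]
    for (s in seq_len(nrow(segs))) {
      feats[[length(feats) + 1]] <- vapply(
        bands, function(b) band_power(segs[s, ], fs, b[1], b[2]), numeric(1)
      )
      subj <- c(subj, coh$subject_ids[i])
    }
  }
  fm <- log(do.call(rbind, feats))
  n <- nrow(fm)
  within <- c(); between <- c()
  for (a in 1:(n - 1)) for (b in (a + 1):n) {
    r <- stats::cor(fm[a, ], fm[b, ])
    if (subj[a] == subj[b]) within <- c(within, r) else between <- c(between, r)
  }
  expect_gt(mean(within), mean(between))
})

test_that("cohorts round-trip through the delimited-file surface", {
  coh <- tiny_cohort(subjects = 2, segments = 1, n_channels = 2)
  dir <- tempfile("cohort")
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(back$subject_ids, coh$subject_ids)
  expect_equal(back$labels, coh$labels)
  expect_equal(back$records[[1]], coh$records[[1]], tolerance = 1e-6)
  unlink(dir, recursive = TRUE)
})
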