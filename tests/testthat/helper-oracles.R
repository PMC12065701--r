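# Independent brute-force oracles, written as plain loops from the method's
# published definitions (edge tables re-transcribed here on purpose, so a
# transcription slip in the package constants would be caught).

oracle_edges <- list(
  list(c(1, 2), c(1, 3), c(1, 4), c(1, 6), c(1, 7), c(1, 9), c(1, 10), c(1, 11)),
  list(c(11, 2), c(11, 3), c(11, 5), c(11, 6), c(11, 8), c(11, 9), c(11, 10), c(11, 1)),
  list(c(3, 4), c(3, 5), c(4, 6), c(5, 6), c(6, 7), c(6, 8), c(7, 9), c(8, 9)),
  list(c(1, 4), c(1, 7), c(4, 6), c(7, 6), c(6, 5), c(6, 8), c(5, 11), c(8, 11)),
  list(c(2, 1), c(2, 3), c(2, 11), c(1, 6), c(11, 6), c(10, 9), c(10, 1), c(10, 11)),
  list(c(6, 1), c(6, 3), c(6, 11), c(6, 9), c(6, 4), c(6, 7), c(6, 8), c(6, 5)),
  list(c(1, 2), c(2, 11), c(11, 10), c(10, 1), c(1, 3), c(3, 11), c(11, 9), c(9, 1))
)

# straight-line enumeration of the nine GHPat steps
brute_ghpat <- function(signal) {
  xi <- length(signal)
  mu <- mean(signal)
  counts <- integer(256)
  for (i in 1:(xi - 10)) {
    P <- signal[i:(i + 10)]
    dists <- vapply(1:7, function(h) {
      nodes <- sort(unique(unlist(oracle_edges[[h]])))
      abs(mu - mean(P[nodes]))
    }, numeric(1))
    ix <- which.min(dists)
    code <- 0
    for (q in 1:8) {
      e <- oracle_edges[[ix]][[q]]
      if (P[e[1]] - P[e[2]] >= 0) code <- code + 2^(q - 1)
    }
    counts[code + 1] <- counts[code + 1] + 1
  }
  counts
}

# exhaustive-distance weighted kNN with the same published tie rules
brute_knn <- function(train_x, train_y, test_x, k) {
  apply(test_x, 1, function(z) {
    d <- rowSums(abs(sweep(train_x, 2, z)))
    nb <- order(d)[1:k] # order() is stable: ties keep index order
    dz <- d[nb] == 0
    if (any(dz)) {
      ys <- train_y[nb][dz]
      return(if (sum(ys == 1) * 2 >= length(ys)) 1L else 2L)
    }
    w <- 1 / d[nb]^2
    w1 <- sum(w[train_y[nb] == 1]); w2 <- sum(w[train_y[nb] == 2])
    if (w1 >= w2) 1L else 2L
  })
}

# element-wise mode with ties to the lower class id
brute_mode <- function(vectors) {
  m <- do.call(cbind, vectors)
  apply(m, 1, function(v) {
    tab <- table(v)
    as.integer(names(tab)[which.max(tab)]) # which.max: first max = lower id
  })
}

# crude band power via the periodogram (independent of signal::butter)
band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  ps <- abs(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  sel <- f >= lo & f <= hi
  mean(ps[sel])
}

# small deterministic cohort shared by pipeline-level tests
tiny_cohort <- function(effect = 1, seed = 7, n_channels = 4,
                        subjects = 4, segments = 2) {
  generate_cohort(synthetic_cohort_config(
    n_subjects_per_class = subjects, segments_per_subject = segments,
    n_channels = n_channels, band_gain_effect = effect, seed = seed
  ))
}
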