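# Weighted kNN and the LOSO engine.

test_that("squared-inverse voting follows the worked arithmetic", {
  # train {0 -> 1, 1 -> 1, 4 -> 2}, test 2.5, k = 3:
  # class 1 weight 1/6.25 + 1/2.25, class 2 weight 1/2.25 -> class 1
  p <- knn_classify(matrix(c(0, 1, 4)), c(1, 1, 2), matrix(2.5), k = 3)
  expect_equal(as.integer(p), 1L)
  s <- attr(p, "score1")
  w1 <- 1 / 2.5^2 + 1 / 1.5^2; w2 <- 1 / 1.5^2
  expect_equal(s, w1 / (w1 + w2))
})

test_that("k = 1 reduces to the nearest neighbour", {
  set.seed(30)
  tr <- matrix(rnorm(40), 20)
  y <- rep(1:2, 10)
  te <- matrix(rnorm(10), 5)
  p <- knn_classify(tr, y, te, k = 1)
  nn <- apply(te, 1, function(z) y[which.min(rowSums(abs(sweep(tr, 2, z))))])
  expect_equal(as.integer(p), as.integer(nn))
})

test_that("zero-distance training points dominate the vote", {
  tr <- matrix(c(0, 0.1, 0.2, 5), 4)
  p <- knn_classify(tr, c(2, 1, 1, 1), matrix(0), k = 4)
  expect_equal(as.integer(p), 2L) # exact match outvotes 3 near neighbours
})

test_that("invalid classifier inputs are rejected", {
  tr <- matrix(rnorm(10), 5)
  expect_error(knn_classify(tr, rep(1:2, len = 5), matrix(0, 1, 2), k = 6),
               "exceeds")
  expect_error(knn_classify(tr, rep(3L, 5), matrix(0), k = 2), "coded 1")
})

test_that("knn_classify agrees with the exhaustive brute-force oracle", {
  set.seed(31)
  for (i in 1:50) {
    ntr <- sample(12:100, 1)
    d <- sample(1:8, 1)
    k <- sample(1:10, 1)
    tr <- matrix(round(rnorm(ntr * d), 2), ntr) # rounding provokes ties
    y <- sample(1:2, ntr, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- 1:2
    te <- matrix(round(rnorm(6 * d), 2), 6)
    expect_equal(as.integer(knn_classify(tr, y, te, k = k)),
                 as.integer(brute_knn(tr, y, te, k)))
  }
})

test_that("LOSO folds partition segments by subject", {
  coh <- tiny_cohort(subjects = 3, segments = 2, n_channels = 2)
  ds <- build_channel_dataset(coh$records, coh$labels, coh$subject_ids, "Fp1")
  res <- loso_cv(ds, selection_control(method = "none"), seed = 2)
  expect_s3_class(res, "loso_result")
  expect_length(res$predicted, 12)
  expect_true(all(res$predicted %in% 1:2))
  expect_setequal(res$fold_subjects, coh$subject_ids)
  # every segment predicted exactly once, in original order
  expect_equal(res$truth, ds$y)
  expect_equal(res$subjects, ds$subjects)
})

test_that("a strongly separated cohort is classified near-perfectly", {
  # large class effect: LOSO accuracy should be at or near 100%
  # k = 3: with only 6 same-class training segments per fold, k = 10 would
  # force at least 4 opposite-class votes into every neighbourhood
  coh <- tiny_cohort(effect = 2, subjects = 4, segments = 2, n_channels = 2)
  ds <- build_channel_dataset(coh$records, coh$labels, coh$subject_ids, "Fp2")
  res <- loso_cv(ds, selection_control(method = "none"), k = 3, seed = 2)
  expect_gte(mean(res$predicted == res$truth), 0.95)
})

test_that("mixed-label subjects are rejected before CV", {
  x <- matrix(rnorm(40), 4)
  expect_error(new_channel_dataset(x, c(1, 2, 1, 2), c("a", "a", "b", "b"), "C3"),
               "mixed labels")
})

test_that("stratified k-fold engine covers every segment once", {
  coh <- tiny_cohort(subjects = 3, segments = 2, n_channels = 2)
  ds <- build_channel_dataset(coh$records, coh$labels, coh$subject_ids, "Fp1")
  res <- kfold_cv(ds, selection_control(method = "none"), nfold = 4, seed = 5)
  expect_length(res$predicted, 12)
  expect_true(all(res$predicted %in% 1:2))
  res2 <- kfold_cv(ds, selection_control(method = "none"), nfold = 4, seed = 5)
  expect_identical(res$predicted, res2$predicted)
})
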