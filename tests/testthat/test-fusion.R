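# IMV voting, metrics, greedy selection and region summaries.

test_that("IMV sorts by accuracy and takes element-wise modes", {
  truth <- c(1, 1, 2, 2)
  ch <- list(c1 = c(1, 1, 2, 2), c2 = c(1, 2, 2, 2), c3 = c(1, 1, 1, 2))
  v <- imv_vote(ch, truth)
  expect_length(v, 1) # n = 3 only
  expect_equal(as.integer(v$n3), c(1, 1, 2, 2))
  expect_error(imv_vote(ch[1:2], truth), "at least 3")
  expect_error(imv_vote(c(ch, list(c(1, 2))), truth), "same length")
})

test_that("20 channels produce 18 voted results; identical inputs pass through", {
  set.seed(40)
  truth <- sample(1:2, 30, replace = TRUE)
  ch <- replicate(20, sample(1:2, 30, replace = TRUE), simplify = FALSE)
  v <- imv_vote(ch, truth)
  expect_length(v, 18)
  expect_equal(vapply(v, attr, integer(1), "n_channels"), 3:20,
               ignore_attr = TRUE)
  same <- replicate(5, truth, simplify = FALSE)
  v <- imv_vote(same, truth)
  for (vv in v) expect_equal(as.integer(vv), truth)
})

test_that("voted vectors match a brute-force mode oracle", {
  set.seed(41)
  for (i in 1:50) {
    nch <- sample(3:9, 1)
    len <- sample(5:40, 1)
    truth <- sample(1:2, len, replace = TRUE)
    ch <- replicate(nch, sample(1:2, len, replace = TRUE), simplify = FALSE)
    v <- imv_vote(ch, truth)
    acc <- vapply(ch, function(p) mean(p == truth), numeric(1))
    ord <- order(-acc, seq_along(ch))
    for (n in 3:nch) {
      expect_equal(as.integer(v[[paste0("n", n)]]),
                   as.integer(brute_mode(ch[ord[1:n]])))
    }
  }
})

test_that("metrics reproduce their defining formulas", {
  m <- compute_metrics(rep(1:2, c(4, 4)), rep(1:2, c(4, 4)))
  expect_equal(m$accuracy, 100)
  expect_equal(m$geometric_mean, 100)
  expect_equal(m$cohens_kappa, 100)
  # counts TP=3 FN=1 TN=2 FP=2
  pred <- c(1, 1, 1, 2, 1, 1, 2, 2)
  tru <- c(1, 1, 1, 1, 2, 2, 2, 2)
  m <- compute_metrics(pred, tru)
  expect_equal(c(m$TP, m$FN, m$TN, m$FP), c(3, 1, 2, 2))
  expect_equal(m$accuracy, 62.5)
  expect_equal(m$geometric_mean, 100 * sqrt(0.75 * 0.5))
  expect_error(compute_metrics(integer(0), integer(0)), "empty")
})

test_that("metric identities hold for random confusion tables", {
  set.seed(42)
  for (i in 1:30) {
    n <- sample(20:100, 1)
    tru <- sample(1:2, n, replace = TRUE)
    pred <- ifelse(runif(n) < 0.3, 3 - tru, tru)
    if (length(unique(tru)) < 2) next
    m <- compute_metrics(pred, tru)
    expect_equal(m$TP + m$TN + m$FP + m$FN, n)
    expect_equal(m$accuracy, 100 * (m$TP + m$TN) / n)
    sens <- m$TP / (m$TP + m$FN); spec <- m$TN / (m$TN + m$FP)
    expect_equal(m$geometric_mean, 100 * sqrt(sens * spec))
    expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
    # kappa against the standard contingency formula
    po <- (m$TP + m$TN) / n
    pe <- ((m$TP + m$FP) * (m$TP + m$FN) + (m$FN + m$TN) * (m$FP + m$TN)) / n^2
    expect_equal(m$cohens_kappa, 100 * (po - pe) / (1 - pe))
  }
})

test_that("rank-based AUC matches an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(43)
  tru <- sample(1:2, 60, replace = TRUE)
  sc <- runif(60) + (tru == 1) * 0.4
  m <- compute_metrics(ifelse(sc > 0.7, 1, 2), tru, scores = sc)
  ref <- suppressMessages(pROC::auc(pROC::roc(
    response = tru, predictor = sc, levels = c(2, 1), direction = "<"
  )))
  expect_equal(m$auc, 100 * as.numeric(ref))
})

test_that("greedy selection picks the overall most accurate candidate", {
  set.seed(44)
  truth <- sample(1:2, 25, replace = TRUE)
  ch <- replicate(6, ifelse(runif(25) < 0.4, 3 - truth, truth),
                  simplify = FALSE)
  names(ch) <- paste0("C", 1:6)
  v <- imv_vote(ch, truth)
  fr <- greedy_best(ch, v, truth)
  expect_s3_class(fr, "fusion_report")
  expect_length(fr$accuracies, 10) # 6 + 4
  best_channel <- max(fr$accuracies[1:6])
  ult_acc <- 100 * mean(fr$ultimate == truth)
  expect_equal(ult_acc, max(fr$accuracies))
  expect_gte(ult_acc, best_channel)
  # a perfect channel always wins (or ties into a perfect vote)
  ch$C1 <- truth
  fr <- greedy_best(ch, imv_vote(ch, truth), truth)
  expect_equal(max(fr$accuracies), 100)
  expect_equal(as.integer(fr$ultimate), truth)
})

test_that("region averages reproduce the reference channel summaries", {
  acc <- stats::setNames(rep(70, 20), ghpat_montage())
  acc[c("P3", "P4")] <- c(77.50, 78.15)
  acc[c("C3", "C4", "Cz")] <- c(78.10, 64.65, 67.33)
  reg <- region_average(acc)
  expect_equal(unname(reg["parietal"]), 77.83)
  expect_equal(unname(reg["central"]), 70.03)
  expect_equal(unname(reg["occipital"]), 70)
  expect_error(region_average(acc[-1]), "Fp1")
  # degenerate: identical channels give identical regions
  flat <- region_average(stats::setNames(rep(81.25, 20), ghpat_montage()))
  expect_true(all(flat == 81.25))
})
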