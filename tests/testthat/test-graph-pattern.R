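# GHPat core: blocks, subgraph selection, bit coding, histograms.

test_that("subgraph tables have the published structure", {
  sg <- gh_subgraphs()
  expect_length(sg, 7)
  for (s in sg) {
    expect_equal(nrow(s$edges), 8)
    expect_true(all(s$edges >= 1 & s$edges <= 11))
    expect_equal(s$node_count, length(s$nodes))
  }
  expect_equal(vapply(sg, `[[`, integer(1), "node_count"),
               c(9L, 9L, 7L, 7L, 7L, 9L, 6L))
  # edge-for-edge agreement with the independently transcribed tables
  for (h in 1:7) {
    expect_equal(unname(sg[[h]]$edges),
                 t(vapply(oracle_edges[[h]], identity, numeric(2))),
                 ignore_attr = TRUE)
  }
  js <- jsonlite::fromJSON(gh_subgraphs_json(), simplifyVector = FALSE)
  expect_length(js, 7)
  expect_equal(js[[3]]$node_count, 7)
})

test_that("make_blocks produces all overlapping 11-sample windows", {
  b <- make_blocks(as.numeric(1:21))
  expect_equal(nrow(b), 11)
  b2 <- make_blocks(as.numeric(1:12))
  expect_equal(nrow(b2), 2)
  expect_equal(unname(b2[1, ]), as.numeric(1:11))
  expect_equal(unname(b2[2, ]), as.numeric(2:12))
  expect_error(make_blocks(1:10), "too short")
  expect_error(make_blocks(c(1:11, NA)), "non-finite")
})

test_that("subgraph selection minimizes the node-mean distance", {
  s <- select_subgraph(rep(3, 11), 3)
  expect_equal(s$distances, rep(0, 7))
  expect_equal(s$selected, 1) # tie -> lowest id
  # increasing ramp: block 1..11 against the mean of 1..21
  s <- select_subgraph(as.numeric(1:11), mean(1:21))
  expect_equal(s$local_means[1:2], c(53 / 9, 55 / 9))
  expect_equal(s$selected, 2)
  # decreasing ramp: block 21..11 against the mean of 21..1
  s <- select_subgraph(as.numeric(21:11), mean(21:1))
  expect_equal(s$selected, 2)
})

test_that("literal mean mode reproduces the printed formulas", {
  blk <- c(5, 1, 4, 2, 8, 3, 9, 7, 6, 2, 1)
  s <- select_subgraph(blk, 4, mu_mode = "literal")
  expect_equal(s$local_means[3], s$local_means[1]) # printed duplication
  expect_equal(s$local_means[7],
               mean(blk[c(1, 3, 4, 5, 6, 7, 8, 9, 11)]))
  sn <- select_subgraph(blk, 4, mu_mode = "nodeset")
  expect_equal(sn$local_means[7], mean(blk[c(1, 2, 3, 9, 10, 11)]))
})

test_that("block coding follows the directed edges, LSB first", {
  expect_equal(encode_block(rep(1, 11), 3), 255) # sgn(0) = 1 on every edge
  expect_equal(encode_block(as.numeric(1:11), 2), 255) # all edges leave the max
  expect_equal(encode_block(as.numeric(11:1), 2), 0) # all edges leave the min
  # shift invariance: codes depend on differences only
  set.seed(3)
  for (rep in 1:10) {
    blk <- rnorm(11)
    h <- sample(7, 1)
    expect_equal(encode_block(blk + 17.3, h), encode_block(blk, h))
  }
  expect_error(encode_block(1:5, 1), "exactly 11")
  expect_error(encode_block(1:11, 9), "1..7")
})

test_that("ghpat_transform returns a conserved 256-bin histogram", {
  h <- ghpat_transform(rep(2.5, 40))
  expect_length(h, 256)
  expect_equal(unname(h[["255"]]), 30)
  expect_equal(sum(h), 30)
  set.seed(11)
  for (n in c(11, 25, 100)) {
    x <- rnorm(n)
    h <- ghpat_transform(x)
    expect_equal(sum(h), n - 10)
    expect_true(all(h >= 0))
    expect_identical(h, ghpat_transform(x)) # deterministic
  }
})

test_that("ghpat_transform matches the brute-force enumeration", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(11:500, 1)
    x <- rnorm(n)
    expect_equal(unname(ghpat_transform(x)), brute_ghpat(x))
  }
})

test_that("feature map codes stay in byte range and drive the histogram", {
  set.seed(5)
  x <- rnorm(300)
  fm <- ghpat_feature_map(x)
  expect_length(fm, 290)
  expect_true(all(fm >= 0 & fm <= 255))
  expect_equal(unname(ghpat_transform(x)), tabulate(fm + 1L, 256))
})

test_that("1-D LBP baseline has the classic shape", {
  h <- lbp1d_baseline(rep(1, 30))
  expect_equal(unname(h[["255"]]), 22)
  expect_equal(sum(h), 22)
  # strictly increasing: right neighbours >= centre, left neighbours below
  h <- lbp1d_baseline(as.numeric(1:50))
  expect_equal(sum(h > 0), 1)
  expect_equal(unname(h[["240"]]), 42) # bits 5..8 set -> 2^4+...+2^7
  set.seed(2)
  x <- rnorm(60)
  expect_equal(sum(lbp1d_baseline(x)), 52)
  expect_error(lbp1d_baseline(1:8), "too short")
})
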