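test_that("clustering error equals exhaustive permutation matching", {
  expect_equal(clustering_error(c(1, 2, 1, 2), c(1, 2, 1, 2)), 0L)
  expect_equal(clustering_error(c(2, 1, 2, 1), c(1, 2, 1, 2)), 0L)  # relabeled
  # every labeling with n = 6, K = 3 against a fixed truth
  y <- c(1L, 1L, 2L, 2L, 3L, 3L)
  grid <- as.matrix(expand.grid(rep(list(1:3), 6)))
  for (i in seq(1, nrow(grid), by = 7)) {          # systematic subsample
    yh <- as.integer(grid[i, ])
    expect_equal(clustering_error(yh, y), oracle_clustering_error(yh, y, 3))
  }
  expect_error(clustering_error(c(0, 1), c(1, 1)), "positive")
  expect_error(clustering_error(1:3, 1:4), "length")
})

test_that("Hungarian matching agrees with exhaustive enumeration for larger K", {
  set.seed(15)
  for (i in 1:60) {
    K <- sample(7:8, 1)                            # forces the Hungarian path
    n <- sample(20:60, 1)
    yh <- sample(seq_len(K), n, TRUE)
    y <- sample(seq_len(K), n, TRUE)
    expect_equal(clustering_error(yh, y), oracle_clustering_error(yh, y, K))
  }
})

test_that("accuracy is the complement of the error rate", {
  expect_equal(accuracy(c(1, 2, 1, 2), c(1, 2, 1, 2)), 1)
  expect_equal(accuracy(c(1, 2, 1, 1), c(1, 2, 1, 2)), 0.75)
  set.seed(8)
  for (i in 1:25) {
    n <- sample(5:40, 1); K <- sample(2:5, 1)
    yh <- sample(seq_len(K), n, TRUE); y <- sample(seq_len(K), n, TRUE)
    expect_equal(accuracy(yh, y) + clustering_error(yh, y) / n, 1)
  }
})

test_that("adjusted Rand index: identities, hand values, pair-counting oracle", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  # contingency [[1,1],[1,1]]: hand computation gives a negative value
  y1 <- c(1, 1, 2, 2); y2 <- c(1, 2, 1, 2)
  expect_equal(adjusted_rand_index(y1, y2), oracle_ari_pairs(y1, y2))
  set.seed(12)
  for (i in 1:30) {
    n <- sample(6:25, 1)
    a <- sample(1:3, n, TRUE); b <- sample(1:4, n, TRUE)
    expect_equal(adjusted_rand_index(a, b), oracle_ari_pairs(a, b),
                 tolerance = 1e-12)
  }
})

test_that("ARI of independent random partitions is centered at zero", {
  set.seed(77)
  aris <- replicate(500, adjusted_rand_index(sample(1:3, 60, TRUE),
                                             sample(1:3, 60, TRUE)))
  expect_lt(abs(mean(aris)), 3 * sd(aris) / sqrt(500))
})

test_that("ARI matches an independently implemented reference", {
  skip_if_not_installed("mclust")
  set.seed(21)
  for (i in 1:40) {
    n <- sample(8:50, 1)
    a <- sample(1:4, n, TRUE); b <- sample(1:3, n, TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
})

test_that("midranks: printed benchmark row, ties, direction, rank-sum invariant", {
  # distinct values: a permutation of 1..8 summing to 36
  r <- rank_with_ties(c(14, 6, 11, 7, 15, 17, 21, 22), "lower_better")
  expect_setequal(r, 1:8)
  expect_equal(sum(r), 36)
  # benchmark row with a four-way tie at 44: each tied method gets 2.5
  row <- c(44, 88, 44, 45, 66, 80, 44, 44)
  r2 <- rank_with_ties(row, "lower_better")
  expect_equal(unname(r2[row == 44]), rep(2.5, 4))
  expect_equal(sum(r2), 36)
  expect_equal(rank_with_ties(c(5, 5, 5), "lower_better"), rep(2, 3))
  expect_equal(rank_with_ties(c(0.9, 0.1), "higher_better"), c(1, 2))
  set.seed(30)
  for (i in 1:1000) {
    m <- sample(2:12, 1)
    v <- sample(1:4, m, TRUE)                     # plenty of ties
    expect_equal(sum(rank_with_ties(v, "lower_better")), m * (m + 1) / 2)
  }
})

test_that("regret rescales each row to [0,1] with the printed-cell example", {
  # Brain row: IF-PCA error 11, min 6, max 21 -> regret 5/15
  row <- c(14, 6, 11, 7, 14, 17, 21, 21)
  rg <- regret(row, "lower_better")
  expect_equal(rg[3], 5 / 15)
  expect_equal(min(rg), 0); expect_equal(max(rg), 1)
  expect_equal(regret(c(3, 3, 3), "lower_better"), c(0, 0, 0))
  acc <- c(0.9, 0.5, 0.7)
  expect_equal(regret(acc, "higher_better"), c(0, 1, 0.5))
})

test_that("summary rows of the bundled benchmarks are reproduced to printed precision", {
  s3 <- summarize_table(microarray_error_table(), "lower_better")
  got3 <- setNames(s3$rank_mean, s3$method)
  expect_equal(unname(got3[c("k-means", "SpecGem", "IF-PCA", "IF-PCA(X)",
                             "VAE", "VAE(X)", "IF-VAE", "IF-VAE(X)")]),
               c(4.3, 6.1, 2.65, 3.9, 5.7, 5.8, 4.3, 3.25), tolerance = 1e-10)
  reg3 <- setNames(s3$regret_mean, s3$method)
  expect_equal(unname(round(reg3, 2)),
               c(0.43, 0.69, 0.18, 0.26, 0.60, 0.65, 0.46, 0.31))

  s6 <- summarize_table(scrna_accuracy_table(), "higher_better",
                        exclude = "SC3")
  got6 <- setNames(s6$rank_mean, s6$method)
  expect_equal(unname(round(got6, 2)),
               c(3.50, 2.75, 3.00, 2.75, 5.38, 3.62))
  reg6 <- setNames(s6$regret_mean, s6$method)
  expect_equal(unname(round(reg6, 2)), c(0.50, 0.37, 0.40, 0.28, 0.90, 0.53))
  # a single-row table collapses to that row's ranks/regrets
  one <- matrix(c(2, 5, 3), 1, dimnames = list("d", c("a", "b", "c")))
  s1 <- summarize_table(one, "lower_better")
  expect_equal(s1$rank_mean, c(1, 3, 2))
  expect_equal(s1$regret_mean, c(0, 1, 1 / 3))
})

test_that("summaries refuse tables with missing cells unless the method is excluded", {
  expect_error(summarize_table(scrna_accuracy_table(), "higher_better"),
               "SC3")
  expect_silent(summarize_table(scrna_accuracy_table(), "higher_better",
                                exclude = "SC3"))
})

test_that("clustering error is invariant to cluster-identity permutations", {
  set.seed(41)
  for (i in 1:25) {
    K <- sample(2:5, 1); n <- sample(10:30, 1)
    yh <- sample(seq_len(K), n, TRUE); y <- sample(seq_len(K), n, TRUE)
    sig <- sample(seq_len(K))
    expect_equal(clustering_error(sig[yh], y), clustering_error(yh, y))
  }
})
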