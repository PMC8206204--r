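test_that("signed-rank maps match exact enumeration and edge contracts", {
  # z approximation vs exact enumeration for n = 6
  d <- c(1, 2, 3, 4, 5, -6)
  p_exact <- exact_signed_rank_p(d)
  # cross-check the enumeration against the signed-rank distribution
  expect_equal(p_exact, 2 * (1 - psignrank(14, 6)))
  expect_equal(p_exact, 28 / 64)
  a <- array(d, c(6, 1, 1)); b <- array(0, c(6, 1, 1))
  sm <- signed_rank_map(a, b)
  expect_lt(abs(sm$p_point[1, 1] - p_exact), 0.05)
  expect_gt(sm$z[1, 1], 0)
  # identical inputs: z = 0, p = 1 everywhere
  x <- array(rnorm(5 * 2 * 3), c(5, 2, 3))
  sm0 <- signed_rank_map(x, x)
  expect_true(all(sm0$z == 0))
  expect_true(all(sm0$p_point == 1))
  # fewer than 5 subjects rejected
  expect_error(signed_rank_map(array(c(-1, 1), c(2, 1, 1)), 0),
               class = "invalid_argument")
})

test_that("cluster permutation agrees with exhaustive sign-flip enumeration", {
  set.seed(11)
  for (rep in 1:3) {
    d <- matrix(rnorm(5 * 3, mean = c(1.2, 1.0, 0.4)), 5, 3, byrow = TRUE)
    p_or <- exact_cluster_p(d)
    res <- cluster_permutation(array(d, c(5, 1, 3)), 0,
                               n_permutations = 4000, seed = rep)
    p_pkg <- min_cluster_p(res)
    expect_lt(abs(p_pkg - p_or), 0.02 + 1e-12)
  }
})

test_that("the permutation p floor is exactly 2/n_permutations", {
  # strong common effect: observed mass beats every permutation
  set.seed(2)
  d <- matrix(rnorm(24 * 12, mean = 3), 24, 12)
  res <- cluster_permutation(array(d, c(24, 1, 12)), 0,
                             n_permutations = 1000, seed = 5)
  expect_equal(min_cluster_p(res), 2 / 1000)
  res2 <- cluster_permutation(array(d, c(24, 1, 12)), 0,
                              n_permutations = 10000, seed = 5)
  expect_equal(min_cluster_p(res2), 2e-04)
  # identical conditions: no suprathreshold point, no clusters
  x <- array(rnorm(6 * 2 * 4), c(6, 2, 4))
  res3 <- cluster_permutation(x, x, neighbors = channel_neighbors(cbind(0:1, 0)),
                              n_permutations = 200, seed = 1)
  expect_length(res3$clusters, 0L)
  expect_equal(min_cluster_p(res3), 1)
})

test_that("permuting subject order leaves cluster statistics unchanged", {
  set.seed(3)
  a <- array(rnorm(7 * 1 * 10, mean = 0.8), c(7, 1, 10))
  b <- array(rnorm(7 * 1 * 10), c(7, 1, 10))
  r1 <- cluster_permutation(a, b, n_permutations = 300, seed = 9)
  ord <- sample(7)
  r2 <- cluster_permutation(a[ord, , , drop = FALSE],
                            b[ord, , , drop = FALSE],
                            n_permutations = 300, seed = 9)
  expect_equal(vapply(r1$clusters, `[[`, 0, "mass"),
               vapply(r2$clusters, `[[`, 0, "mass"))
  expect_equal(r1$z, r2$z)
})

test_that("multichannel clustering respects the neighbor graph", {
  # two adjacent channels + one isolated: the isolated channel cannot join
  pos <- cbind(c(0, 1, 10), c(0, 0, 0))
  nb <- channel_neighbors(pos)
  expect_true(2L %in% nb[[1]] && 1L %in% nb[[2]])
  expect_length(nb[[3]], 0L)
  set.seed(4)
  d <- array(rnorm(8 * 3 * 6), c(8, 3, 6))
  d[, 1:2, 3:4] <- d[, 1:2, 3:4] + 3   # shared effect on the adjacent pair
  d[, 3, 6] <- d[, 3, 6] + 3           # separate effect on the isolated one
  res <- cluster_permutation(d, 0, neighbors = nb, n_permutations = 200,
                             seed = 2)
  sizes <- vapply(res$clusters, function(cl) nrow(cl$members), 0L)
  expect_gte(length(res$clusters), 2L)
  big <- res$clusters[[which.max(sizes)]]
  expect_true(all(big$members[, 1] %in% c(1L, 2L)))
})

test_that("dependent-samples effect size follows its definition", {
  expect_equal(cohens_d_dependent(c(0, 1, 2)), 1.0)
  expect_equal(cohens_d_dependent(c(-2, -1, 1, 2)), 0)
  expect_error(cohens_d_dependent(rep(3, 4)), class = "undefined_effect")
  expect_error(cohens_d_dependent(1), class = "invalid_argument")
})

test_that("cross-method Spearman correlation recovers perfect and null cases", {
  set.seed(6)
  ia <- matrix(rnorm(12 * 3), 12, 3)
  r <- spearman_cluster_corr(ia, ia, n_permutations = 200, seed = 1)
  expect_true(all(r$rho == 1))
  r2 <- spearman_cluster_corr(ia, -ia, n_permutations = 200, seed = 1)
  expect_true(all(r2$rho == -1))
  # false-positive calibration on independent indices
  nb <- channel_neighbors(cbind(seq_len(4), 0))
  hits <- vapply(1:40, function(i) {
    set.seed(100 + i)
    x <- matrix(rnorm(40 * 4), 40, 4)
    y <- matrix(rnorm(40 * 4), 40, 4)
    res <- spearman_cluster_corr(x, y, neighbors = nb,
                                 n_permutations = 1000, seed = i)
    any(vapply(res$clusters, `[[`, 0, "p") <= 0.05)
  }, TRUE)
  expect_lte(mean(hits), 0.07)
})
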