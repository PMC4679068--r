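test_that("re-ordered jackknife matches hand-traced examples", {
  # leave-one-out rankings agree with the full ranking: D = C in rank order
  r1 <- reordered_jackknife(rbind(c(0, 2), c(4, 6)))
  expect_equal(r1$D, rbind(c(0, 2), c(4, 6)))
  expect_equal(r1$delta_hat, c(1, 5))

  # rankings differ per held-out column
  r2 <- reordered_jackknife(rbind(c(5, 0), c(1, 4)))
  expect_equal(r2$D, rbind(c(5, 4), c(1, 0)))
  expect_equal(r2$delta_hat, c(4.5, 0.5))

  # constant matrix: any permutation of identical values
  r3 <- reordered_jackknife(matrix(7, 4, 6))
  expect_equal(r3$delta_hat, rep(7, 4))
})

test_that("each re-ordered column is a permutation of the original, so the grand mean is conserved", {
  set.seed(61)
  for (rep in 1:5) {
    C <- matrix(rnorm(30 * 8), 30, 8)
    res <- reordered_jackknife(C)
    for (j in 1:8) expect_equal(sort(res$D[, j]), sort(C[, j]))
    expect_equal(mean(res$delta_hat), mean(C), tolerance = 1e-13)
  }
})

test_that("random partitions have near-equal fold sizes and are seed-deterministic", {
  p <- random_partition(4, 2, seed = 1)
  expect_equal(sort(p$sizes), c(2L, 2L))
  p <- random_partition(5, 2, seed = 1)
  expect_equal(sort(p$sizes), c(2L, 3L))
  p1 <- random_partition(20, 6, seed = 42)
  p2 <- random_partition(20, 6, seed = 42)
  expect_identical(p1, p2)
  expect_lte(diff(range(p1$sizes)), 1L)
  expect_error(random_partition(5, 1), "K")
  expect_error(random_partition(5, 6), "K")
})

test_that("K-fold collapse takes fold means and preserves row means for equal folds", {
  C <- matrix(c(1, 2, 3, 4), 1, 4)
  part <- structure(list(assignments = c(1L, 1L, 2L, 2L), K = 2L,
                         sizes = c(2L, 2L)), class = "fold_partition")
  expect_equal(kfold_collapse(C, part), matrix(c(1.5, 3.5), 1, 2))

  Cc <- matrix(5, 3, 4)
  expect_equal(kfold_collapse(Cc, part), matrix(5, 3, 2))

  set.seed(71)
  C <- matrix(rnorm(10 * 12), 10, 12)
  part <- random_partition(12, 4, seed = 2)
  expect_equal(rowMeans(kfold_collapse(C, part)), rowMeans(C),
               tolerance = 1e-13)

  empty <- structure(list(assignments = rep(1L, 4), K = 2L,
                          sizes = c(4L, 0L)), class = "fold_partition")
  expect_error(kfold_collapse(C[, 1:4], empty), "at least one column")
  expect_error(kfold_collapse(C, part <- random_partition(5, 2, seed = 3)),
               "covers")
})

test_that("projack conserves the grand mean exactly for any dividing K and is seed-deterministic", {
  set.seed(81)
  C <- matrix(rnorm(20 * 12), 20, 12)
  for (K in c(2, 3, 4, 6)) {
    fit <- projack(C, K = K, n_partitions = 7, seed = 5)
    expect_equal(mean(fit$delta_hat), mean(C), tolerance = 1e-13)
  }
  f1 <- projack(C, K = 4, n_partitions = 11, seed = 9)
  f2 <- projack(C, K = 4, n_partitions = 11, seed = 9)
  expect_identical(f1, f2)

  # constant matrix in, constant estimates out
  fit <- projack(matrix(-3, 6, 10), K = 5, n_partitions = 4, seed = 1)
  expect_equal(fit$delta_hat, rep(-3, 6))

  # rank_to_feature is the ascending sort of the row means
  fit <- projack(C, K = 3, n_partitions = 5, seed = 4)
  expect_identical(fit$rank_to_feature, order(rowMeans(C)))
  expect_true(all(sort(fit$rank_to_feature) == 1:20))
})

test_that("the plain re-ordered jackknife is unbiased at every rank under a constant mean", {
  set.seed(91)
  n_sims <- 2000
  m <- 10
  n <- 20
  acc <- matrix(0, n_sims, m)
  for (s in seq_len(n_sims)) {
    C <- matrix(rnorm(m * n, sd = sqrt(n)), m, n)
    acc[s, ] <- reordered_jackknife(C)$delta_hat
  }
  means <- colMeans(acc)
  ses <- apply(acc, 2, sd) / sqrt(n_sims)
  expect_true(all(abs(means) <= 4 * ses))
})

test_that("well-separated features keep their row means: no shrinkage of outliers", {
  set.seed(101)
  n <- 20
  C <- rbind(rnorm(n, -10, sqrt(n)), rnorm(n, 10, sqrt(n)))
  fit <- projack(C, K = 5, n_partitions = 50, seed = 7)
  # ordering never flips at 20 sd separation, so delta_hat equals the sorted
  # row means exactly
  expect_equal(fit$delta_hat, sort(rowMeans(C)), tolerance = 1e-12)
  expect_lt(abs(fit$delta_hat[1] + 10), 4)
  expect_lt(abs(fit$delta_hat[2] - 10), 4)
})

test_that("projack shrinks the naive top statistic under the null", {
  set.seed(111)
  n_sims <- 150
  top_naive <- top_projack <- numeric(n_sims)
  for (s in seq_len(n_sims)) {
    C <- simulate_pseudo_matrix(rep(0, 30), n = 25)
    top_naive[s] <- max(rowMeans(C))
    top_projack[s] <- abs(projack(C, K = 5, n_partitions = 20)$delta_hat[30])
  }
  expect_lt(mean(top_projack), mean(top_naive) - 0.5)
})
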