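test_that("scenario mean vectors have the prescribed shapes", {
  expect_equal(make_mu("box", 5), c(-2, -1, 0, 1, 2))
  expect_equal(make_mu("normal_quantile", 3), qnorm(c(1, 2, 3) / 4))
  expect_equal(make_mu("normal_quantile", 3)[1], -0.6744898, tolerance = 1e-6)
  mu <- make_mu("sparse", 100)
  expect_equal(mu[1:2], c(-6, -3))
  expect_equal(mu[3:99], rep(0, 97))
  expect_equal(mu[100], 2)
  expect_equal(make_mu("null", 7), rep(0, 7))
  expect_false(is.unsorted(make_mu("normal_quantile", 50)))
  expect_error(make_mu("sparse", 2), "m >= 3")
})

test_that("simulated pseudo-matrices have the advertised moments and row-mean correlation", {
  C <- simulate_pseudo_matrix(rep(0, 100), n = 50, seed = 13)
  expect_equal(dim(C), c(100, 50))
  expect_lt(abs(mean(C)), 0.15)
  expect_lt(abs(var(as.vector(C)) - 50), 2.5)
  # row means are N(mu, 1)
  expect_lt(abs(var(rowMeans(C)) - 1), 0.5)

  # equicorrelation of row means under rho = 0.4
  set.seed(14)
  R <- 10000
  rm2 <- matrix(0, R, 2)
  for (r in seq_len(R)) {
    rm2[r, ] <- rowMeans(simulate_pseudo_matrix(c(0, 0), n = 4, rho = 0.4))
  }
  expect_lt(abs(cor(rm2[, 1], rm2[, 2]) - 0.4), 0.03)

  expect_error(simulate_pseudo_matrix(0, 5, rho = 1), "rho")
  expect_error(simulate_pseudo_matrix(0, 5, rho = -0.1), "rho")
})

test_that("the Monte-Carlo oracle matches closed-form expected ranked means", {
  expect_equal(true_delta(3.2, n_sims = 5, seed = 1)$delta, 3.2)

  # delta_(i) is the expected *label* at rank i: identically 0 when all mu = 0
  td <- true_delta(c(0, 0), n_sims = 2000, seed = 15)
  expect_identical(td$delta, c(0, 0))
  # ... whereas the expected naive *minimum statistic* is -1/sqrt(pi)
  set.seed(115)
  zmin <- vapply(1:40000, function(s) min(rnorm(2)), numeric(1))
  expect_lt(abs(mean(zmin) - oracle_min2_null), 4 * sd(zmin) / sqrt(40000))

  td <- true_delta(c(0, 3), n_sims = 40000, seed = 16)
  expect_lt(abs(td$delta[1] - oracle_min2_shift(3)), 3 * td$mc_se[1])
  expect_equal(oracle_min2_shift(3), 0.0508, tolerance = 1e-3)

  # per-draw label sums are conserved by sorting, so exactly for the average
  mu <- make_mu("box", 20)
  td <- true_delta(mu, n_sims = 500, seed = 17)
  expect_equal(sum(td$delta), sum(mu), tolerance = 1e-10)
  # monotone within MC tolerance
  expect_true(all(diff(td$delta) >= -2 * (td$mc_se[-1] + td$mc_se[-20])))
})

test_that("AMSE instantiates its formula", {
  expect_equal(amse(c(1, 2, 3, 4), c(1, 2, 3, 4), T = 2), 0)
  # single sim, m = 4, T = 2: (e1^2 + e4^2)/2
  est <- c(1.5, 2, 3, 3.2)
  truth <- c(1, 2, 3, 4)
  expect_equal(amse(est, truth, T = 2), (0.5^2 + 0.8^2) / 2)
  # constant offset b at all ranks -> b^2
  expect_equal(amse(truth + 0.3, truth, T = 4), 0.09)
  # multiple sims average
  mat <- rbind(truth, truth + 1)
  expect_equal(amse(mat, truth, T = 2), 0.5)
  expect_error(amse(est, truth, T = 3), "even")
  expect_error(amse(est, truth, T = 6), "even|<=")
})

test_that("LD-style propagation assigns r * mu within blocks and zeroes weak proxies", {
  spec <- data.frame(pos = c(3, 12), mu = c(6, -8))
  g <- simulate_gwas_like(20, n_blocks = 2, block_rho = 0.5,
                          causal_spec = spec, seed = 18)
  expect_equal(g$mu[3], 6)
  expect_equal(g$mu[4], 0.5 * 6)   # adjacent proxy: r = 0.5
  expect_equal(g$mu[2], 0.5 * 6)
  expect_equal(g$mu[5], 0.25 * 6)              # r^2 = 0.0625 > 0.05: kept
  expect_equal(g$mu[6], 0)                     # r^2 = 0.0156 <= 0.05: zeroed
  expect_equal(g$mu[12], -8)

  # r^2 <= 0.05 cutoff: rho = 0.4 kills proxies at distance >= 2
  g2 <- simulate_gwas_like(20, 2, 0.4, data.frame(pos = 5, mu = 6), seed = 19)
  expect_equal(g2$mu[4], 0.4 * 6)
  expect_equal(g2$mu[6], 0.4 * 6)
  expect_equal(g2$mu[3], 0)   # r = 0.16, r^2 = 0.0256 <= 0.05
  expect_equal(g2$mu[7], 0)

  # no LD: only causal features carry effects
  g3 <- simulate_gwas_like(20, 2, 0, data.frame(pos = c(3, 12), mu = c(6, -8)),
                           seed = 20)
  expect_equal(which(g3$mu != 0), c(3L, 12L))

  expect_error(simulate_gwas_like(20, 2, 0.5,
                                  data.frame(pos = c(3, 5), mu = c(1, 2))),
               "overlapping")
})

test_that("within-block z correlation follows the AR(1) structure", {
  set.seed(21)
  R <- 4000
  z1 <- z2 <- matrix(0, R, 2)
  for (r in seq_len(R)) {
    g <- simulate_gwas_like(4, 1, 0.6, data.frame(pos = 1, mu = 0))
    z1[r, ] <- g$z[1:2]
    z2[r, ] <- g$z[c(1, 3)]
  }
  expect_lt(abs(cor(z1[, 1], z1[, 2]) - 0.6), 0.05)       # lag 1
  expect_lt(abs(cor(z2[, 1], z2[, 2]) - 0.36), 0.05)      # lag 2
})

test_that("scenario harness reports naive order-statistic bias and near-unbiased projack", {
  # naive: E[z_(m)] for m = 100 nulls is about 2.51
  spec <- scenario_spec("null", m = 100, n = 50, n_sims = 200, seed = 22)
  res <- run_scenario(spec, method = "naive", oracle_sims = 2000)
  expect_s3_class(res, "metrics_table")
  expect_named(res, c("rank", "e_z_naive", "e_delta_hat", "true_delta",
                      "bias", "mse"))
  expect_equal(res$e_z_naive, res$e_delta_hat)
  expect_lt(abs(res$e_z_naive[100] - 2.51), 0.12)
  expect_lt(res$e_z_naive[1], 0)
  expect_true(all(res$mse >= res$bias^2 - 1e-9))

  # projack at desk scale: bias well inside the naive bias
  spec <- scenario_spec("null", m = 30, n = 30, n_sims = 100, seed = 23)
  resp <- run_scenario(spec, method = "projack",
                       method_params = list(K = 5, n_partitions = 25),
                       oracle_sims = 2000)
  expect_lt(max(abs(resp$bias)), 0.35)
  resn <- run_scenario(spec, method = "naive", oracle_sims = 2000)
  expect_lt(max(abs(resp$bias)), 0.5 * max(abs(resn$bias)))

  # conditional likelihood zeroes everything under the null at a strict c
  resc <- run_scenario(spec, method = "cond_mle",
                       method_params = list(c = 5.45), oracle_sims = 500)
  expect_equal(max(abs(resc$e_delta_hat)), 0)

  # independent variant runs and conserves the grand mean on average
  resi <- run_scenario(spec, method = "independent_projack",
                       method_params = list(K = 5, B = 200),
                       oracle_sims = 500)
  expect_lt(abs(mean(resi$e_delta_hat)), 0.1)
})
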