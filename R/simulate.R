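# Synthetic-data generation and the evaluation harness: scenario mean
# vectors, equicorrelated pseudo-matrices, the Monte-Carlo oracle for the
# true expected ranked effects, per-rank bias/MSE benchmarking, the AMSE
# summary, and a scaled-down GWAS-like generator with LD-style effect
# propagation.

#' Scenario mean vectors
#'
#' The standard benchmark configurations (all sorted ascending):
#' `null` (all zero), `sparse` (`-6, -3, 0 x (m-3), 2`: two strong negative
#' outliers and one moderate positive among nulls), `normal_quantile`
#' (`qnorm(i/(m+1))`), and `box` (equally spaced on `[-2, 2]`).
#'
#' @param name scenario name.
#' @param m number of features (>= 3 for `sparse`).
#' @return numeric vector of length `m`, nondecreasing.
#' @export
make_mu <- function(name = c("null", "sparse", "normal_quantile", "box"), m) {
  name <- match.arg(name)
  if (!is.numeric(m) || length(m) != 1L || m < 1L) {
    stop("`m` must be a positive integer", call. = FALSE)
  }
  m <- as.integer(m)
  switch(name,
    null = rep(0, m),
    sparse = {
      if (m < 3L) stop("sparse scenario needs m >= 3", call. = FALSE)
      c(-6, -3, rep(0, m - 3L), 2)
    },
    normal_quantile = qnorm(seq_len(m) / (m + 1)),
    box = seq(-2, 2, length.out = m)
  )
}

#' Simulate a pseudo-matrix with equicorrelated rows
#'
#' Columns are drawn independently; within a column the `m` entries are
#' jointly normal with mean `mu_i`, variance `n`, and common pairwise
#' correlation `rho`. Row means are then `N(mu_i, 1)` with inter-row
#' correlation `rho`, mimicking a pseudo-matrix built from `n` samples.
#'
#' @param mu mean vector (length m).
#' @param n number of columns; also the per-entry variance.
#' @param rho common inter-row correlation in `[0, 1)`.
#' @param seed optional integer seed.
#' @return numeric m x n matrix.
#' @export
simulate_pseudo_matrix <- function(mu, n, rho = 0, seed = NULL) {
  check_z(mu, arg = "mu")
  if (!is.numeric(n) || length(n) != 1L || n < 2L) {
    stop("`n` must be a single integer >= 2", call. = FALSE)
  }
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho >= 1) {
    stop("`rho` must lie in [0, 1)", call. = FALSE)
  }
  m <- length(mu)
  n <- as.integer(n)
  with_seed(seed, {
    E <- matrix(rnorm(m * n), m, n)
    if (rho > 0) {
      shared <- rnorm(n)  # one factor per column, common to all rows
      E <- sqrt(1 - rho) * E + sqrt(rho) * matrix(shared, m, n, byrow = TRUE)
    }
    sqrt(n) * E + mu
  })
}

# z ~ N(mu, 1) with common inter-feature correlation rho (the row-mean
# distribution implied by simulate_pseudo_matrix)
simulate_z <- function(mu, rho = 0) {
  e <- rnorm(length(mu))
  if (rho > 0) e <- sqrt(1 - rho) * e + sqrt(rho) * rnorm(1L)
  mu + e
}

#' Monte-Carlo oracle for the true expected ranked effects
#'
#' Estimates `delta_(i) = E(mu_(i))` by repeatedly drawing `z ~ N(mu, I)`,
#' sorting ascending, and recording which `mu` lands at each rank.
#'
#' @param mu mean vector.
#' @param n_sims number of Monte-Carlo draws (>= 1000 recommended).
#' @param seed optional integer seed.
#' @return list of class `true_delta` with `delta` (length-m, rank order),
#'   `n_sims`, and `mc_se` (per-rank Monte-Carlo standard error).
#' @export
true_delta <- function(mu, n_sims = 10000, seed = NULL) {
  check_z(mu, arg = "mu")
  if (!is.numeric(n_sims) || length(n_sims) != 1L || n_sims < 1L) {
    stop("`n_sims` must be >= 1", call. = FALSE)
  }
  m <- length(mu)
  n_sims <- as.integer(n_sims)
  res <- with_seed(seed, {
    acc <- numeric(m)
    acc2 <- numeric(m)
    for (s in seq_len(n_sims)) {
      lab <- mu[order(rnorm(m) + mu)]
      acc <- acc + lab
      acc2 <- acc2 + lab^2
    }
    list(acc = acc, acc2 = acc2)
  })
  delta <- res$acc / n_sims
  var_hat <- pmax(0, res$acc2 / n_sims - delta^2)
  structure(list(delta = delta, n_sims = n_sims,
                 mc_se = sqrt(var_hat / n_sims)),
            class = "true_delta")
}

#' Simulation scenario specification
#'
#' @param name one of `"null"`, `"sparse"`, `"normal_quantile"`, `"box"`,
#'   `"custom"` (the latter requires `mu`).
#' @param m number of features.
#' @param n number of samples per simulated pseudo-matrix.
#' @param rho common inter-feature correlation in `[0, 1)`.
#' @param n_sims number of simulated datasets.
#' @param seed optional integer seed for the whole scenario run.
#' @param mu mean vector for `name = "custom"` (must be nondecreasing).
#' @return list of class `scenario_spec`.
#' @export
scenario_spec <- function(name = c("null", "sparse", "normal_quantile", "box",
                                   "custom"),
                          m = 100, n = 50, rho = 0, n_sims = 1000,
                          seed = NULL, mu = NULL) {
  name <- match.arg(name)
  if (name == "custom") {
    if (is.null(mu)) stop("custom scenario requires `mu`", call. = FALSE)
    check_z(mu, arg = "mu")
    if (is.unsorted(mu)) {
      stop("`mu` must be nondecreasing (sorted convention)", call. = FALSE)
    }
    m <- length(mu)
  } else {
    mu <- make_mu(name, m)
  }
  if (rho < 0 || rho >= 1) stop("`rho` must lie in [0, 1)", call. = FALSE)
  structure(list(name = name, m = as.integer(m), mu = mu, n = as.integer(n),
                 rho = rho, n_sims = as.integer(n_sims), seed = seed),
            class = "scenario_spec")
}

#' Run a scenario study
#'
#' Simulates `n_sims` datasets under `spec`, applies the chosen estimation
#' method, and reports per-rank operating characteristics against the
#' Monte-Carlo oracle [true_delta()]: the expected naive order statistic
#' `E[z_(i)]`, the expected estimate `E[delta_hat_(i)]`, the true
#' `delta_(i)`, bias, and MSE.
#'
#' `projack` simulates full pseudo-matrices ([simulate_pseudo_matrix()]);
#' the other methods work from z vectors drawn with the same mean and
#' correlation structure.
#'
#' @param spec a [scenario_spec()].
#' @param method estimation method.
#' @param method_params optional overrides: `K`, `n_partitions` (projack),
#'   `B` (independent projack), `c` (conditional likelihood threshold).
#' @param oracle_sims Monte-Carlo draws for the true-delta oracle.
#' @return data.frame of class `metrics_table` with columns `rank`,
#'   `e_z_naive`, `e_delta_hat`, `true_delta`, `bias`, `mse`.
#' @export
run_scenario <- function(spec,
                         method = c("projack", "independent_projack",
                                    "cond_mle", "naive"),
                         method_params = list(), oracle_sims = 10000L) {
  if (!inherits(spec, "scenario_spec")) {
    stop("`spec` must be created by scenario_spec()", call. = FALSE)
  }
  method <- match.arg(method)
  mp <- modifyList(list(K = 5, n_partitions = 50, B = 1000, c = 1.96),
                   method_params)
  m <- spec$m

  with_seed(spec$seed, {
    td <- true_delta(spec$mu, n_sims = oracle_sims)
    sum_z <- sum_d <- sum_sq <- numeric(m)
    for (s in seq_len(spec$n_sims)) {
      if (method == "projack") {
        C <- simulate_pseudo_matrix(spec$mu, spec$n, spec$rho)
        z <- rowMeans(C)
        dh <- projack(C, K = mp$K, n_partitions = mp$n_partitions)$delta_hat
      } else {
        z <- simulate_z(spec$mu, spec$rho)
        dh <- switch(method,
          independent_projack =
            independent_projack(z, K = mp$K, B = mp$B)$delta_hat,
          cond_mle = cond_mle(z, mp$c)$mu_tilde[order(z)],
          naive = sort(z))
      }
      sum_z <- sum_z + sort(z)
      sum_d <- sum_d + dh
      sum_sq <- sum_sq + (dh - td$delta)^2
    }
    e_d <- sum_d / spec$n_sims
    out <- data.frame(rank = seq_len(m),
                      e_z_naive = sum_z / spec$n_sims,
                      e_delta_hat = e_d,
                      true_delta = td$delta,
                      bias = e_d - td$delta,
                      mse = sum_sq / spec$n_sims)
    class(out) <- c("metrics_table", "data.frame")
    out
  })
}

#' AMSE: mean squared error over the most extreme ranks
#'
#' Averages, over simulations, the squared estimation error at the `T/2`
#' lowest and `T/2` highest ranks:
#' `AMSE = (1/S) sum_s (1/T) [ sum_{i=1}^{T/2} (dh_{i,s} - delta_i)^2 +
#' sum_{i=m-T/2+1}^{m} (dh_{i,s} - delta_i)^2 ]`.
#'
#' @param delta_hat_by_sim S x m matrix of per-rank estimates (or a single
#'   length-m vector).
#' @param true_delta length-m vector of true expected ranked effects.
#' @param T even number of extreme ranks to evaluate (`T/2` per tail).
#' @return single numeric value.
#' @export
amse <- function(delta_hat_by_sim, true_delta, T) {
  if (is.vector(delta_hat_by_sim)) {
    delta_hat_by_sim <- matrix(delta_hat_by_sim, nrow = 1L)
  }
  m <- ncol(delta_hat_by_sim)
  if (length(true_delta) != m) {
    stop("`true_delta` must have one value per rank", call. = FALSE)
  }
  if (!is.numeric(T) || length(T) != 1L || T < 2L || T %% 2 != 0 || T > m) {
    stop("`T` must be even, >= 2, and <= m", call. = FALSE)
  }
  idx <- c(seq_len(T / 2), seq(m - T / 2 + 1L, m))
  err <- sweep(delta_hat_by_sim[, idx, drop = FALSE], 2L, true_delta[idx])
  mean(err^2)
}

#' GWAS-like z vector with LD-style effect propagation
#'
#' A parametric stand-in for genotype-based simulation: `m` features are laid
#' out in `n_blocks` contiguous blocks with AR(1)-style within-block
#' correlation `r_{i,i'} = block_rho^|i - i'|` (zero across blocks). Each
#' causal feature carries its specified effect `mu`; a non-causal feature in
#' the same block inherits the proxy effect `mu_{i'} = r_{i,i'} * mu_i`
#' provided `r^2 > 0.05`, and zero otherwise -- the standard LD-propagation
#' rule. `z` is drawn as `N(mu_truth, Sigma_block)`.
#'
#' @param m total number of features.
#' @param n_blocks number of contiguous correlation blocks.
#' @param block_rho within-block lag-1 correlation in `[0, 1)`.
#' @param causal_spec data.frame with columns `pos` (feature index) and `mu`
#'   (effect size); at most one causal feature per block.
#' @param seed optional integer seed.
#' @return list with `z` (named numeric), `mu` (true per-feature effects
#'   after propagation), and `block` (block index per feature).
#' @export
simulate_gwas_like <- function(m, n_blocks, block_rho, causal_spec,
                               seed = NULL) {
  if (!is.numeric(m) || m < 1L || !is.numeric(n_blocks) || n_blocks < 1L ||
      n_blocks > m) {
    stop("need 1 <= n_blocks <= m", call. = FALSE)
  }
  if (block_rho < 0 || block_rho >= 1) {
    stop("`block_rho` must lie in [0, 1)", call. = FALSE)
  }
  if (!is.data.frame(causal_spec) || is.null(causal_spec$pos) ||
      is.null(causal_spec$mu)) {
    stop("`causal_spec` must be a data.frame with columns `pos` and `mu`",
         call. = FALSE)
  }
  m <- as.integer(m)
  pos <- as.integer(causal_spec$pos)
  if (any(pos < 1L | pos > m)) {
    stop("causal positions must lie in 1..m", call. = FALSE)
  }
  block <- sort(rep_len(seq_len(as.integer(n_blocks)), m))
  if (anyDuplicated(block[pos])) {
    stop("overlapping causal blocks: at most one causal feature per block",
         call. = FALSE)
  }

  mu <- numeric(m)
  for (k in seq_along(pos)) {
    idx <- which(block == block[pos[k]])
    r <- block_rho^abs(idx - pos[k])  # r = 1 at the causal feature itself
    mu[idx] <- ifelse(r^2 > 0.05, r * causal_spec$mu[k], 0)
  }

  z <- with_seed(seed, {
    e <- numeric(m)
    for (b in unique(block)) {
      idx <- which(block == b)
      eb <- numeric(length(idx))
      eb[1L] <- rnorm(1L)
      if (length(idx) > 1L) {
        innov <- rnorm(length(idx) - 1L, sd = sqrt(1 - block_rho^2))
        for (t in 2:length(idx)) eb[t] <- block_rho * eb[t - 1L] + innov[t - 1L]
      }
      e[idx] <- eb
    }
    mu + e
  })
  names(z) <- paste0("f", seq_len(m))
  list(z = z, mu = mu, block = block)
}

#' K-sweep squared-error analysis of a reported effect table
#'
#' For each `K` in `K_grid`: augment the observed z statistics to the full
#' scan size with artificial null-like statistics ([augment_z()]), run the
#' independent projack, map the per-rank estimates back to the observed
#' features, rescale to the log-odds-ratio scale using the implied Wald
#' standard errors, and score against the replication odds ratios
#' ([squared_error_vs_replication()]).
#'
#' @param effect_table data.frame with columns `z`, `or_naive`, `or_repl`
#'   (e.g. [psoriasis_table1()]).
#' @param K_grid numeric vector of K values (> 1).
#' @param m_total total number of features in the original scan.
#' @param B independent-projack repetitions per K.
#' @param seed optional integer seed (one stream across the whole sweep).
#' @return data.frame with columns `K` and `beta_mse`.
#' @export
psoriasis_k_sweep <- function(effect_table, K_grid = 2:12, m_total = 48000,
                              B = 1000, seed = NULL) {
  for (col in c("z", "or_naive", "or_repl")) {
    if (is.null(effect_table[[col]])) {
      stop("`effect_table` must contain column `", col, "`", call. = FALSE)
    }
  }
  if (any(K_grid <= 1)) stop("all K values must exceed 1", call. = FALSE)
  z <- effect_table$z
  se <- se_from_wald(log(effect_table$or_naive), z)
  m_top <- length(z)

  with_seed(seed, {
    beta_mse <- vapply(K_grid, function(K) {
      z_aug <- augment_z(z, m_total)
      fit <- independent_projack(z_aug, K = K, B = B)
      delta_feat <- feature_estimates(fit)[seq_len(m_top)]
      beta_hat <- rescale_estimates(delta_feat, se)$beta_hat
      squared_error_vs_replication(beta_hat, effect_table)
    }, numeric(1))
    data.frame(K = as.numeric(K_grid), beta_mse = beta_mse)
  })
}
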