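# Independent oracles used to freeze expected values. Each is written from
# the defining formula, not from the package code paths it checks.

# Exhaustive grid argmax of the conditional log-likelihood over
# sign(z) * [0, |z| + 1], plain arithmetic (no log-tail tricks).
oracle_cond_mle <- function(z, c, step = 1e-4) {
  az <- abs(z)
  grid <- seq(0, az + 1, by = step)
  ll <- dnorm(az - grid, log = TRUE) -
    log(pnorm(grid - c) + pnorm(-c - grid))
  sign(z) * grid[which.max(ll)]
}

# Literal double-loop pseudo-matrix from the definition
# c_ij = n z_i - (n-1) sqrt(n/(n-1)) z_{i[-j]}.
oracle_pseudo_matrix <- function(X, y, statf) {
  n <- ncol(X)
  m <- nrow(X)
  z <- vapply(seq_len(m), function(i) statf(X[i, ], y), numeric(1))
  C <- matrix(NA_real_, m, n)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      zl <- statf(X[i, -j], y[-j])
      C[i, j] <- n * z[i] - (n - 1) * sqrt(n / (n - 1)) * zl
    }
  }
  C
}

# Score statistic for the slope of a simple linear association:
# sqrt(n) * Pearson correlation.
oracle_score_z <- function(x, y) sqrt(length(x)) * cor(x, y)

# Closed forms for the expected minimum label with m = 2 means:
# E[mu_(1)] for mu = (0, 0) is -1/sqrt(pi); for mu = (0, Delta) the labels
# swap with probability Phi(-Delta/sqrt(2)), so E[mu_(1)] = Delta * P(swap).
oracle_min2_null <- -1 / sqrt(pi)
oracle_min2_shift <- function(Delta) Delta * pnorm(-Delta / sqrt(2))
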