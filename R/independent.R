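# The independent projack: correction from the z vector alone.

#' Independent projack
#'
#' Winner's-curse correction when only the vector of z statistics is
#' available. Each repetition mimics one random K-fold split of the matrix
#' projack: a perturbed "training" vector `z' = z + gamma` with
#' `gamma_i ~ iid N(0, 1/(K-1))` determines the ranking, and the
#' anti-correlated "test" vector `c = K*z - (K-1)*z'` (equivalently
#' `z - (K-1)*gamma`) supplies the values read off at each rank. Averaging
#' the re-ordered `c` over `B` repetitions gives `delta_hat`. By construction
#' `cov(z'_i, c_i) = 0` when `Var(z_i) = 1`, so the ranking noise is
#' independent of the recorded values, which is what removes the ranking
#' bias.
#'
#' `K` need not be an integer here: any `K > 1` is valid, trading bias
#' (small K) against variance (large K) exactly as the fold count does in the
#' matrix projack; values in 5-10 are typical.
#'
#' @param z numeric vector of z statistics (optionally named).
#' @param K fold-equivalent parameter, any real `> 1`.
#' @param B number of repetitions (>= 1; at least 1000 recommended).
#' @param seed optional integer seed.
#' @return object of class `ranked_estimates`. The ranking reported in
#'   `rank_to_feature` is the ascending sort of the observed `z`.
#' @examples
#' z <- rnorm(100)
#' fit <- independent_projack(z, K = 5, B = 1000, seed = 1)
#' max(abs(fit$delta_hat)) < max(abs(z))  # extremes are pulled in
#' @export
independent_projack <- function(z, K = 5, B = 1000, seed = NULL) {
  check_z(z)
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K <= 1) {
    stop("`K` must be a single number > 1 (variance of gamma is 1/(K-1))",
         call. = FALSE)
  }
  if (!is.numeric(B) || length(B) != 1L || B < 1L) {
    stop("`B` must be >= 1", call. = FALSE)
  }
  B <- as.integer(B)
  m <- length(z)
  ids <- feature_ids(z)
  zv <- unname(as.numeric(z))

  acc <- with_seed(seed, {
    a <- numeric(m)
    sd_gamma <- sqrt(1 / (K - 1))
    for (b in seq_len(B)) {
      gamma <- rnorm(m, 0, sd_gamma)
      z_train <- zv + gamma
      c_test <- zv - (K - 1) * gamma
      a <- a + c_test[order(z_train)]  # re-ordering uses z', never z
    }
    a
  })

  new_ranked_estimates(delta_hat = acc / B,
                       rank_to_feature = order(zv),
                       ids = ids, z = zv, K = K, n_reps = B,
                       seed = seed, method = "independent_projack")
}

#' Augment a vector of top z statistics with artificial null-like statistics
#'
#' When only the most significant statistics of a large scan are reported,
#' the correction still needs the full ranking context. This pads the
#' observed vector out to `m_total` features by appending
#' `m_total - length(z_top)` artificial statistics placed at standard normal
#' quantiles of an evenly spaced grid, `qnorm(i / (m_add + 1))`,
#' `i = 1..m_add` -- the expected shape of a null z sample.
#'
#' @param z_top numeric vector of observed (reported) z statistics.
#' @param m_total total number of features in the original scan.
#' @return named numeric vector of length `m_total`: the observed statistics
#'   first, then the artificial block (ids `artificial_1`, ...). The
#'   artificial block has mean zero by symmetry.
#' @examples
#' augment_z(c(4.2, 5.1), m_total = 11)
#' @export
augment_z <- function(z_top, m_total) {
  check_z(z_top, arg = "z_top")
  m_top <- length(z_top)
  if (!is.numeric(m_total) || length(m_total) != 1L || m_total <= m_top) {
    stop(sprintf("`m_total` must exceed length(z_top) = %d", m_top),
         call. = FALSE)
  }
  m_add <- as.integer(m_total) - m_top
  filler <- qnorm(seq_len(m_add) / (m_add + 1))
  ids <- c(feature_ids(z_top), paste0("artificial_", seq_len(m_add)))
  stats::setNames(c(unname(z_top), filler), ids)
}
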