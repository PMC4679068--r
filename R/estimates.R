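# ranked_estimates: container for corrected per-rank effect estimates.

new_ranked_estimates <- function(delta_hat, rank_to_feature, ids, z, K,
                                 n_reps, seed, method) {
  stopifnot(length(delta_hat) == length(z),
            length(rank_to_feature) == length(z),
            all(sort(rank_to_feature) == seq_along(z)))
  structure(list(delta_hat = as.numeric(delta_hat),
                 rank_to_feature = as.integer(rank_to_feature),
                 ids = ids, z = z, K = K, n_reps = n_reps,
                 seed = seed, method = method),
            class = "ranked_estimates")
}

#' Coerce ranked estimates to a data frame
#'
#' One row per rank (ascending): the realized feature at that rank, its
#' observed z, and the corrected estimate `delta_hat`.
#'
#' @param x a `ranked_estimates` object.
#' @param ... unused.
#' @return data.frame with columns `rank`, `feature_id`, `z`, `delta_hat`.
#' @export
as.data.frame.ranked_estimates <- function(x, ...) {
  data.frame(rank = seq_along(x$delta_hat),
             feature_id = x$ids[x$rank_to_feature],
             z = x$z[x$rank_to_feature],
             delta_hat = x$delta_hat,
             stringsAsFactors = FALSE)
}

#' Per-feature corrected estimates
#'
#' Maps the per-rank estimates back to the original feature order (feature i
#' gets the estimate at the rank it realized).
#'
#' @param x a `ranked_estimates` object.
#' @return named numeric vector in original feature order.
#' @export
feature_estimates <- function(x) {
  stopifnot(inherits(x, "ranked_estimates"))
  inv <- integer(length(x$rank_to_feature))
  inv[x$rank_to_feature] <- seq_along(inv)
  stats::setNames(x$delta_hat[inv], x$ids)
}

#' @export
print.ranked_estimates <- function(x, ...) {
  m <- length(x$delta_hat)
  cat(sprintf("Ranked effect estimates (%s): m = %d, K = %s, reps = %d\n",
              x$method, m, format(x$K), x$n_reps))
  df <- as.data.frame(x)
  show <- if (m > 10L) rbind(utils::head(df, 5L), utils::tail(df, 5L)) else df
  print(show, row.names = FALSE)
  if (m > 10L) cat("  ... (", m - 10L, " ranks omitted)\n", sep = "")
  invisible(x)
}
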