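# Conversion between the z / mu scale and the reporting (log odds ratio)
# scale, and evaluation against replication values.
#
# For a Wald statistic z = beta_hat / SE_hat with beta the natural log odds
# ratio, mu = beta / SE; corrected estimates on the mu scale map back via
# beta = delta_hat * SE. The slight extra bias from SE being estimated is
# ignored, as is standard.

#' Implied Wald standard error
#'
#' Recovers the standard error from a naive estimate and its Wald statistic:
#' `SE = beta_naive / z`.
#'
#' @param beta_naive naive effect estimate(s) (log odds ratio scale).
#' @param z Wald statistic(s); must be nonzero.
#' @return numeric vector of standard errors.
#' @export
se_from_wald <- function(beta_naive, z) {
  if (length(beta_naive) != length(z)) {
    stop("`beta_naive` and `z` must have the same length", call. = FALSE)
  }
  if (any(z == 0)) stop("`z` must be nonzero", call. = FALSE)
  beta_naive / z
}

#' Rescale corrected z-scale estimates to the effect scale
#'
#' @param delta_hat_per_feature corrected estimates on the z/mu scale, in
#'   feature order (see [feature_estimates()]).
#' @param se per-feature standard errors, aligned with `delta_hat_per_feature`.
#' @return list with `beta_hat` (log odds ratio scale) and `or_hat`
#'   (`exp(beta_hat)`).
#' @export
rescale_estimates <- function(delta_hat_per_feature, se) {
  if (length(delta_hat_per_feature) != length(se)) {
    stop("`delta_hat_per_feature` and `se` must have the same length",
         call. = FALSE)
  }
  beta_hat <- as.numeric(delta_hat_per_feature) * as.numeric(se)
  list(beta_hat = beta_hat, or_hat = exp(beta_hat))
}

#' Mean squared error against replication effects
#'
#' Treats the replication odds ratios as a gold standard and returns
#' `mean((beta_hat_i - ln(or_repl_i))^2)` over the evaluated features.
#'
#' @param beta_hat estimates on the log odds ratio scale, aligned with the
#'   rows of `effect_table`.
#' @param effect_table data.frame with at least an `or_repl` column (see
#'   [read_effect_table()]).
#' @return single numeric value.
#' @export
squared_error_vs_replication <- function(beta_hat, effect_table) {
  if (!is.data.frame(effect_table) || is.null(effect_table$or_repl)) {
    stop("`effect_table` must contain an `or_repl` column", call. = FALSE)
  }
  if (length(beta_hat) != nrow(effect_table)) {
    stop("`beta_hat` must have one value per effect_table row", call. = FALSE)
  }
  missing <- !is.finite(effect_table$or_repl) | effect_table$or_repl <= 0
  if (any(missing)) {
    lab <- if (!is.null(effect_table$snp)) effect_table$snp else
      rownames(effect_table)
    stop("replication odds ratio missing or invalid for: ",
         paste(utils::head(lab[missing], 5L), collapse = ", "), call. = FALSE)
  }
  mean((beta_hat - log(effect_table$or_repl))^2)
}
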