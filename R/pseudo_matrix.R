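# Construction of the jackknife pseudo-matrix C from raw data.
#
# For statistic z_i = f(x_i., y) computed on n samples, the pseudo-values are
#   c_ij = n * z_i - (n - 1) * mu_hat_{i[-j]},   mu_hat_{i[-j]} = z_{i[-j]} * sqrt(n/(n-1)),
# where z_{i[-j]} is the statistic recomputed without sample j. The sqrt factor
# restores the n-sample scale of a statistic computed on n-1 samples, so that
# the row means of C approximate z (exactly, for the one-sample mean).

#' Row means of a pseudo-matrix
#'
#' Convenience accessor: the vector of per-feature row means of `C`, which by
#' construction approximates (or, for the one-sample mean statistic, exactly
#' equals) the vector of observed z statistics.
#'
#' @param C numeric matrix (features x samples).
#' @return numeric vector of length `nrow(C)`.
#' @export
row_means <- function(C) {
  check_matrix(C)
  rowMeans(C)
}

# Row-vectorized built-in statistics, recomputed from scratch on the given
# columns. Used by the explicit engine and for the full-sample z.
row_statistic <- function(X, y, statistic) {
  n <- ncol(X)
  switch(statistic,
    one_sample_z = sqrt(n) * rowMeans(X),
    linear_score_z = ,
    trend_z = {
      yc <- y - mean(y)
      syy <- sum(yc^2)
      xc <- X - rowMeans(X)
      sxx <- rowSums(xc^2)
      sxy <- as.vector(xc %*% yc)
      z <- sqrt(n) * sxy / sqrt(sxx * syy)
      z[sxx <= 0 | syy <= 0] <- NaN
      z
    },
    stop(sprintf("unknown statistic '%s'", statistic), call. = FALSE)
  )
}

needs_outcome <- function(statistic) {
  !identical(statistic, "one_sample_z")
}

# Residualize rows of X and y on covariates V (p x n) plus an intercept, once
# on the full sample. Used for linear_score_z only.
residualize <- function(X, y, V) {
  if (!is.matrix(V) || ncol(V) != ncol(X)) {
    stop("`covariates` must be a p x n matrix with one column per sample",
         call. = FALSE)
  }
  qrV <- qr(cbind(1, t(V)))
  list(X = t(qr.resid(qrV, t(X))), y = qr.resid(qrV, y))
}

#' Build the jackknife pseudo-matrix from raw data
#'
#' Constructs the m x n matrix `C` with elements
#' `c_ij = n * z_i - (n - 1) * sqrt(n/(n-1)) * z_{i[-j]}`, where `z_i` is the
#' chosen per-feature statistic on all `n` samples and `z_{i[-j]}` is the same
#' statistic recomputed with sample `j` left out. Row means of `C` reproduce
#' the observed statistics (exactly for `one_sample_z`, closely otherwise),
#' so downstream resampling can operate on `C` alone instead of the raw data.
#'
#' Built-in statistics:
#' \describe{
#'   \item{`one_sample_z`}{`sqrt(n) * mean(x_i)`, for data with known unit
#'     standard deviation. Closed form: `c_ij = sqrt(n) * x_ij`.}
#'   \item{`linear_score_z`}{score statistic for the slope in a simple linear
#'     association of `y` with row `x_i`, equal to `sqrt(n) * cor(x_i, y)`.
#'     If `covariates` is supplied, `X` rows and `y` are residualized on the
#'     covariates (plus intercept) once, on the full sample, before the
#'     leave-one-out construction.}
#'   \item{`trend_z`}{Cochran-Armitage trend statistic for a binary 0/1
#'     outcome versus a numeric (e.g. genotype dosage) row; algebraically
#'     `sqrt(n) * cor(x_i, y)` when `y` is 0/1.}
#' }
#'
#' For the built-ins the leave-one-out statistics are obtained by closed-form
#' downdating of the full-sample sums (engine `"closed_form"`); a literal
#' per-column recomputation (engine `"explicit"`) is kept both as the
#' cross-check path and as the fallback used when `statistic` is a
#' user-supplied `function(x, y)`.
#'
#' @param X numeric m x n matrix, one feature per row, one sample per column.
#' @param y outcome vector of length n; required unless
#'   `statistic = "one_sample_z"`. Must be 0/1 for `trend_z`.
#' @param statistic name of a built-in statistic, or a function `f(x, y)`
#'   returning a scalar z for one feature.
#' @param covariates optional p x n numeric matrix (for `linear_score_z`).
#' @param engine `"closed_form"` (default for built-ins) or `"explicit"`.
#' @return numeric m x n pseudo-matrix with the feature ids of `X` as rownames.
#' @examples
#' X <- matrix(rnorm(5 * 20), 5, 20)
#' C <- build_pseudo_matrix(X, statistic = "one_sample_z")
#' all.equal(row_means(C), sqrt(20) * rowMeans(X))
#' @export
build_pseudo_matrix <- function(X, y = NULL,
                                statistic = c("one_sample_z", "linear_score_z",
                                              "trend_z"),
                                covariates = NULL,
                                engine = c("closed_form", "explicit")) {
  user_stat <- is.function(statistic)
  if (!user_stat) statistic <- match.arg(statistic)
  engine <- match.arg(engine)
  if (user_stat) engine <- "explicit"

  X <- as.matrix(X)
  check_matrix(X, min_cols = 3L, arg = "X")
  m <- nrow(X)
  n <- ncol(X)
  ids <- feature_ids(X, m)

  if (user_stat || needs_outcome(statistic)) {
    if (is.null(y)) stop("`y` is required for this statistic", call. = FALSE)
    if (!is.numeric(y) || length(y) != n || !all(is.finite(y))) {
      stop("`y` must be a finite numeric vector with one value per sample",
           call. = FALSE)
    }
  }
  if (identical(statistic, "trend_z") && !all(y %in% c(0, 1))) {
    stop("`trend_z` requires a binary 0/1 outcome `y`", call. = FALSE)
  }
  if (!is.null(covariates)) {
    if (!identical(statistic, "linear_score_z")) {
      stop("`covariates` are only supported with statistic 'linear_score_z'",
           call. = FALSE)
    }
    adj <- residualize(X, y, as.matrix(covariates))
    X <- adj$X
    y <- adj$y
  }

  C <- if (engine == "closed_form") {
    pseudo_closed_form(X, y, statistic, ids)
  } else {
    pseudo_explicit(X, y, statistic, ids, user_stat)
  }
  rownames(C) <- ids
  colnames(C) <- colnames(X)
  C
}

sample_ids <- function(X) {
  sid <- colnames(X)
  if (is.null(sid)) sid <- paste0("s", seq_len(ncol(X)))
  sid
}

pseudo_closed_form <- function(X, y, statistic, ids) {
  n <- ncol(X)
  m <- nrow(X)
  if (statistic == "one_sample_z") {
    return(sqrt(n) * X)
  }
  # correlation-type statistic: downdate the full-sample sums
  n1 <- n - 1
  Sx <- rowSums(X)
  Sxx <- rowSums(X^2)
  Sxy <- as.vector(X %*% y)
  Sy <- sum(y)
  Syy <- sum(y^2)

  vxx_full <- Sxx - Sx^2 / n
  vyy_full <- Syy - Sy^2 / n
  if (vyy_full <= 0) stop("outcome `y` has zero variance", call. = FALSE)
  if (any(vxx_full <= 0)) {
    stop("feature(s) with zero variance: ",
         paste(utils::head(ids[vxx_full <= 0], 5L), collapse = ", "),
         call. = FALSE)
  }
  z <- sqrt(n) * (Sxy - Sx * Sy / n) / sqrt(vxx_full * vyy_full)

  Ym <- matrix(y, m, n, byrow = TRUE)
  sx <- Sx - X          # recycles Sx down columns: entry (i,j) = Sx[i] - x_ij
  sxx <- Sxx - X^2
  sxy <- Sxy - X * Ym
  sy <- Sy - Ym
  syy <- Syy - Ym^2
  cxx <- sxx - sx^2 / n1
  cyy <- syy - sy^2 / n1
  cxy <- sxy - sx * sy / n1

  flag_degenerate(cxx, cyy, ids, sample_ids(X),
                  tol_x = 1e-10 * pmax(1, vxx_full),
                  tol_y = 1e-10 * max(1, vyy_full))
  Zloo <- sqrt(n1) * cxy / sqrt(cxx * cyy)
  n * z - sqrt(n * n1) * Zloo
}

flag_degenerate <- function(cxx, cyy, ids, sids, tol_x, tol_y) {
  bad_x <- which(cxx <= tol_x, arr.ind = TRUE)
  if (nrow(bad_x)) {
    stop(sprintf(
      "leave-one-out subset has zero variance in x: feature '%s', sample '%s'",
      ids[bad_x[1L, 1L]], sids[bad_x[1L, 2L]]), call. = FALSE)
  }
  bad_y <- which(cyy[1L, ] <= tol_y)
  if (length(bad_y)) {
    stop(sprintf("leave-one-out subset has zero variance in y: sample '%s'",
                 sids[bad_y[1L]]), call. = FALSE)
  }
  invisible(NULL)
}

pseudo_explicit <- function(X, y, statistic, ids, user_stat) {
  n <- ncol(X)
  m <- nrow(X)
  sids <- sample_ids(X)
  z_full <- if (user_stat) {
    vapply(seq_len(m), function(i) statistic(X[i, ], y), numeric(1))
  } else {
    row_statistic(X, y, statistic)
  }
  if (any(!is.finite(z_full))) {
    stop("full-sample statistic is not finite for feature(s): ",
         paste(utils::head(ids[!is.finite(z_full)], 5L), collapse = ", "),
         call. = FALSE)
  }
  Zloo <- matrix(NA_real_, m, n)
  for (j in seq_len(n)) {
    Zloo[, j] <- if (user_stat) {
      vapply(seq_len(m), function(i) statistic(X[i, -j], y[-j]), numeric(1))
    } else {
      row_statistic(X[, -j, drop = FALSE],
                    if (is.null(y)) NULL else y[-j], statistic)
    }
  }
  bad <- which(!is.finite(Zloo), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "leave-one-out statistic undefined (zero variance): feature '%s', sample '%s'",
      ids[bad[1L, 1L]], sids[bad[1L, 2L]]), call. = FALSE)
  }
  n * z_full - sqrt(n * (n - 1)) * Zloo
}
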