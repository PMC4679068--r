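# Internal helpers shared across modules.

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state
# afterwards. seed = NULL means "use the ambient RNG stream as-is", which is
# what nested calls rely on (e.g. projack() seeds once, then draws partitions
# from the running stream).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
      stop("`seed` must be a single finite number, or NULL", call. = FALSE)
    }
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      stats::runif(1L)
    }
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  code
}

check_matrix <- function(C, min_cols = 1L, arg = "C") {
  if (!is.matrix(C) || !is.numeric(C) || nrow(C) < 1L || ncol(C) < min_cols) {
    stop(sprintf("`%s` must be a numeric matrix with >= 1 row and >= %d column(s)",
                 arg, min_cols), call. = FALSE)
  }
  if (!all(is.finite(C))) {
    stop(sprintf("`%s` contains non-finite entries", arg), call. = FALSE)
  }
  invisible(C)
}

check_z <- function(z, arg = "z") {
  if (!is.numeric(z) || length(z) < 1L) {
    stop(sprintf("`%s` must be a numeric vector of length >= 1", arg), call. = FALSE)
  }
  if (!all(is.finite(z))) {
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  }
  invisible(z)
}

# Feature identifiers: rownames/names when present, else f1..fm. Must be unique.
feature_ids <- function(x, m = if (is.matrix(x)) nrow(x) else length(x)) {
  ids <- if (is.matrix(x)) rownames(x) else names(x)
  if (is.null(ids)) {
    ids <- paste0("f", seq_len(m))
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("feature ids must be unique; duplicated: ",
         paste(utils::head(dup, 5L), collapse = ", "), call. = FALSE)
  }
  ids
}
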