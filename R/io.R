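# TSV readers/writers and the bundled case-study fixture. All exchange files
# are tab-delimited UTF-8 with a header row; lines starting with '#' carry
# run metadata and are skipped on read.

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' Read a z-statistic table
#'
#' Expects a TSV with columns `id` (or `snp`, used as the identifier) and
#' `z`; extra columns are passed through.
#'
#' @param path file path.
#' @return validated data.frame with an `id` column first.
#' @export
read_z_table <- function(path) {
  df <- read_tsv_checked(path)
  if (is.null(df$id) && !is.null(df$snp)) df$id <- df$snp
  require_columns(df, c("id", "z"), path)
  if (!is.numeric(df$z)) stop("column `z` in ", path, " is not numeric",
                              call. = FALSE)
  if (any(!is.finite(df$z))) stop("column `z` in ", path,
                                  " has missing/non-finite values", call. = FALSE)
  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup)) {
    stop("duplicate feature id(s) in ", path, ": ",
         paste(utils::head(dup, 5L), collapse = ", "), call. = FALSE)
  }
  df[, c("id", setdiff(names(df), "id"))]
}

#' Read an effect table
#'
#' A Table-1-style record of reported associations: required columns `snp`,
#' `z`, `or_naive`; optional `chrom`, `pos_mb`, `gene`, `p`, `or_repl`.
#' Checks that the naive odds ratios are positive, that `p` (if present) lies
#' in (0, 1], and warns if any `sign(log(or_naive))` disagrees with `sign(z)`.
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
read_effect_table <- function(path) {
  df <- read_tsv_checked(path)
  require_columns(df, c("snp", "z", "or_naive"), path)
  if (!is.numeric(df$z) || !is.numeric(df$or_naive)) {
    stop("columns `z` and `or_naive` in ", path, " must be numeric",
         call. = FALSE)
  }
  if (any(df$or_naive <= 0)) stop("`or_naive` must be positive", call. = FALSE)
  if (!is.null(df$p) && any(df$p <= 0 | df$p > 1)) {
    stop("`p` must lie in (0, 1]", call. = FALSE)
  }
  dup <- unique(df$snp[duplicated(df$snp)])
  if (length(dup)) {
    stop("duplicate snp id(s) in ", path, ": ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad_sign <- sign(log(df$or_naive)) != sign(df$z) & df$z != 0
  if (any(bad_sign)) {
    warning("sign(log(or_naive)) disagrees with sign(z) for: ",
            paste(df$snp[bad_sign], collapse = ", "), call. = FALSE)
  }
  df
}

#' The bundled psoriasis case-control effect table
#'
#' Ten SNPs reported as associated with psoriasis in a 1350-case / 1400-control
#' genome scan of 480,000 markers, with z statistics, p-values, naive odds
#' ratios, and odds ratios from a larger (5000 + 5000) replication study.
#' All replication odds ratios sit closer to 1 than the naive ones -- the
#' winner's curse observed directly. The replication values serve as the gold
#' standard when scoring correction methods.
#'
#' @return data.frame with columns `chrom`, `snp`, `pos_mb`, `gene`, `z`,
#'   `p`, `or_naive`, `or_repl`.
#' @export
psoriasis_table1 <- function() {
  read_effect_table(system.file("extdata", "psoriasis_table1.tsv",
                                package = "projack", mustWork = TRUE))
}

#' Read a feature-by-sample matrix
#'
#' TSV layout: first column feature ids, header row sample ids, numeric body.
#'
#' @param path file path.
#' @return numeric matrix with feature ids as rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv_checked(path)
  if (ncol(df) < 2L) stop("matrix file needs an id column plus data columns",
                          call. = FALSE)
  ids <- as.character(df[[1L]])
  X <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(X)) stop("matrix body in ", path, " is not numeric",
                           call. = FALSE)
  rownames(X) <- ids
  feature_ids(X)
  X
}

#' Write a feature-by-sample matrix as TSV
#' @param X numeric matrix with rownames.
#' @param path output path.
#' @param header optional metadata comment line(s) written first.
#' @export
write_matrix_tsv <- function(X, path, header = NULL) {
  df <- data.frame(id = rownames(X), X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_with_header(df, path, header)
}

run_header <- function(...) {
  fields <- c(...)
  sprintf("# projack %s %s", as.character(utils::packageVersion("projack")),
          paste(names(fields), unname(fields), sep = "=", collapse = " "))
}

write_tsv_with_header <- function(df, path, header = NULL) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a rank table
#'
#' Output format of the correction runs: one row per rank (ascending) with
#' columns `rank`, `feature_id`, `z`, `delta_hat`, preceded by a comment line
#' recording the package version, method, seed, K, and repetition count so
#' every artifact is reproducible.
#'
#' @param est a `ranked_estimates` object.
#' @param path output path.
#' @param full_precision write full double precision instead of 6 significant
#'   digits.
#' @export
write_rank_table <- function(est, path, full_precision = FALSE) {
  stopifnot(inherits(est, "ranked_estimates"))
  df <- as.data.frame(est)
  if (!full_precision) {
    df$z <- signif(df$z, 6)
    df$delta_hat <- signif(df$delta_hat, 6)
  }
  hdr <- run_header(method = est$method, K = format(est$K),
                    reps = est$n_reps,
                    seed = if (is.null(est$seed)) "NA" else format(est$seed))
  write_tsv_with_header(df, path, hdr)
}
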