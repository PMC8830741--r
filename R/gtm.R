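#' Construct a genotype matrix object
#'
#' A `genotype_matrix` holds the observed ternary genotype calls of `N`
#' single cells at `M` SNV loci: 1 = mutation present, 0 = absent, `NA` =
#' unobserved (missing). The fraction of missing entries (eta) is computed
#' on construction and re-used by the model-selection score.
#'
#' @param values integer matrix, cells in rows, loci in columns; entries
#'   must be 0, 1 or `NA`.
#' @param cell_ids optional character vector of row labels (no duplicates);
#'   defaults to `cell_0 ... cell_{N-1}`.
#' @param locus_ids optional character vector of column labels; defaults to
#'   `locus_0 ... locus_{M-1}`.
#' @return an object of class `genotype_matrix` with fields `values`,
#'   `cell_ids`, `locus_ids` and `eta`.
#' @export
genotype_matrix <- function(values, cell_ids = NULL, locus_ids = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "integer"
  N <- nrow(values)
  M <- ncol(values)
  if (N < 1L || M < 1L) {
    stop("genotype matrix must contain at least one cell and one locus")
  }
  bad <- which(!(is.na(values) | values == 0L | values == 1L))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% N) + 1L
    j <- ((bad[1L] - 1L) %/% N) + 1L
    stop(sprintf("invalid genotype code '%s' at cell %d, locus %d (allowed: 0, 1, missing)",
                 values[bad[1L]], i, j))
  }
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(N) - 1L)
  if (is.null(locus_ids)) locus_ids <- paste0("locus_", seq_len(M) - 1L)
  if (length(cell_ids) != N) stop("cell_ids length does not match number of rows")
  if (length(locus_ids) != M) stop("locus_ids length does not match number of columns")
  if (anyDuplicated(cell_ids)) stop("duplicated cell_ids")
  if (anyDuplicated(locus_ids)) stop("duplicated locus_ids")
  dimnames(values) <- NULL
  structure(
    list(values = values,
         cell_ids = as.character(cell_ids),
         locus_ids = as.character(locus_ids),
         eta = mean(is.na(values))),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d cells x %d loci, %.1f%% missing\n",
              nrow(x$values), ncol(x$values), 100 * x$eta))
  invisible(x)
}

#' Fraction of missing entries in a genotype matrix
#'
#' @param gtm a `genotype_matrix`.
#' @return proportion of unobserved entries, in `[0, 1]`.
#' @export
missing_fraction <- function(gtm) {
  stopifnot(inherits(gtm, "genotype_matrix"))
  mean(is.na(gtm$values))
}

#' Read an observed genotype matrix from a delimited text file
#'
#' Parses a plain-text matrix with one row per cell (or per locus with
#' `cells_as_rows = FALSE`) and entries in `{0, 1, missing_code}`. The
#' delimiter is auto-detected as any run of spaces/tabs unless given.
#'
#' @param path file to read.
#' @param missing_code integer token encoding unobserved entries (default 3).
#' @param delimiter explicit field separator; `NULL` splits on whitespace.
#' @param has_header if `TRUE` the first non-empty line holds column labels.
#' @param cells_as_rows if `FALSE` the file is transposed after parsing so
#'   that cells end up in rows.
#' @return a `genotype_matrix` (cells in rows).
#' @export
read_gtm <- function(path, missing_code = 3L, delimiter = NULL,
                     has_header = FALSE, cells_as_rows = TRUE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("empty genotype matrix file: %s", path))
  split1 <- function(x) {
    if (is.null(delimiter)) {
      strsplit(trimws(x), "[ \t]+")
    } else {
      lapply(strsplit(x, delimiter, fixed = TRUE), trimws)
    }
  }
  header <- NULL
  if (has_header) {
    header <- split1(lines[1L])[[1L]]
    lines <- lines[-1L]
    if (!length(lines)) stop("genotype matrix file contains only a header")
  }
  toks <- split1(lines)
  M <- length(toks[[1L]])
  widths <- lengths(toks)
  if (any(widths != M)) {
    r <- which(widths != M)[1L]
    stop(sprintf("ragged matrix: row %d has %d fields, expected %d",
                 r, widths[r], M))
  }
  allowed <- c("0", "1", as.character(missing_code))
  flat <- unlist(toks, use.names = FALSE)
  bad <- which(!(flat %in% allowed))
  if (length(bad)) {
    r <- ((bad[1L] - 1L) %/% M) + 1L
    j <- ((bad[1L] - 1L) %% M) + 1L
    stop(sprintf("unrecognized genotype code '%s' at row %d, column %d (allowed: %s)",
                 flat[bad[1L]], r, j, paste(allowed, collapse = ", ")))
  }
  vals <- matrix(as.integer(flat), nrow = length(toks), ncol = M, byrow = TRUE)
  vals[vals == as.integer(missing_code)] <- NA_integer_
  cell_ids <- NULL
  locus_ids <- NULL
  if (!cells_as_rows) {
    vals <- t(vals)
    if (!is.null(header)) cell_ids <- header
  } else if (!is.null(header)) {
    locus_ids <- header
  }
  genotype_matrix(vals, cell_ids = cell_ids, locus_ids = locus_ids)
}

#' Write a genotype matrix as delimited text
#'
#' Inverse of [read_gtm()] under the default dialect: missing entries are
#' emitted as `missing_code`, no header, cells in rows.
#'
#' @param gtm a `genotype_matrix` (or a plain 0/1/`NA` matrix).
#' @param path output file.
#' @param missing_code integer written for `NA` entries.
#' @param delimiter field separator (default tab).
#' @export
write_gtm <- function(gtm, path, missing_code = 3L, delimiter = "\t") {
  vals <- if (inherits(gtm, "genotype_matrix")) gtm$values else as.matrix(gtm)
  vals[is.na(vals)] <- as.integer(missing_code)
  utils::write.table(vals, file = path, sep = delimiter,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write all artifacts of a converged fit
#'
#' Writes four files sharing `out_prefix`: `_assignments.tsv` (cell id,
#' 1-based cluster index, max posterior), `_subclone_genotypes.tsv` (K x M
#' binary matrix), `_predicted_gtm.tsv` (N x M predicted genotypes, one row
#' per cell) and a run summary in both human-readable (`_summary.txt`) and
#' flat key/value (`_summary.tsv`) form. The two matrices round-trip through
#' [read_gtm()].
#'
#' @param fit a `clonemix_fit` from [fit_em()] or [select_k()].
#' @param out_prefix path prefix for the output files.
#' @return invisibly, the vector of files written.
#' @export
write_results <- function(fit, out_prefix) {
  stopifnot(inherits(fit, "clonemix_fit"))
  dir <- dirname(out_prefix)
  if (!dir.exists(dir)) stop(sprintf("output directory does not exist: %s", dir))
  files <- paste0(out_prefix, c("_assignments.tsv", "_subclone_genotypes.tsv",
                                "_predicted_gtm.tsv", "_summary.txt",
                                "_summary.tsv"))
  assign_df <- data.frame(
    cell_id = fit$cell_ids,
    cluster = fit$assignments,
    posterior = apply(fit$gamma, 1L, max)
  )
  utils::write.table(assign_df, files[1L], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  write_gtm(fit$params$C, files[2L])
  write_gtm(fit$Z, files[3L])
  summary_kv <- c(
    K = fit$params$K,
    alpha = fit$params$alpha,
    beta = fit$params$beta,
    log_likelihood = fit$log_likelihood,
    score = if (is.null(fit$score)) NA_real_ else fit$score,
    n_iter = fit$n_iter
  )
  txt <- c(
    sprintf("subclones (K): %d", fit$params$K),
    sprintf("estimated FPR alpha: %.6f", fit$params$alpha),
    sprintf("estimated FNR beta: %.6f", fit$params$beta),
    sprintf("log-likelihood: %.6f", fit$log_likelihood),
    sprintf("selection score: %s",
            if (is.null(fit$score)) "NA" else sprintf("%.6f", fit$score)),
    sprintf("EM iterations (best run): %d", fit$n_iter)
  )
  writeLines(txt, files[4L])
  utils::write.table(
    data.frame(key = names(summary_kv), value = unname(summary_kv)),
    files[5L], sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(files)
}
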