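#' Sample-by-taxon count table
#'
#' Container for a matrix of non-negative integer sequence counts
#' \eqn{Y_{i,j}} (samples in rows, taxa in columns) together with per-sample
#' library sizes \eqn{s_i}. By definition \eqn{s_i = \sum_j Y_{i,j}}; when the
#' table is a subset of a larger experiment the full library sizes can be
#' supplied, in which case each must be at least the row sum of the subset.
#' Library sizes enter Poisson-type models as an `offset(log(s_i))` and
#' binomial-type models as the number of trials.
#'
#' @param counts numeric matrix of non-negative integers, samples x taxa.
#' @param sample_ids,taxon_ids optional identifier vectors; default to
#'   dimnames or generated labels.
#' @param library_sizes optional per-sample totals; defaults to row sums.
#' @return an object of class `count_table` with elements `counts`,
#'   `sample_ids`, `taxon_ids`, `library_sizes`.
#' @examples
#' ct <- count_table(matrix(c(1, 2, 3, 4), 2, 2))
#' ct$library_sizes  # row sums: 4, 6
#' @export
count_table <- function(counts, sample_ids = NULL, taxon_ids = NULL,
                        library_sizes = NULL) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("counts must be numeric")
  bad <- which(!is.finite(counts) | counts < 0 | abs(counts - round(counts)) > 1e-8)
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(counts))
    stop(sprintf(
      "counts must be non-negative integers; offending cell at row %d, column %d (value %s)",
      rc[1], rc[2], format(counts[bad[1]])))
  }
  storage.mode(counts) <- "double"
  counts <- round(counts)
  n <- nrow(counts); m <- ncol(counts)
  sample_ids <- as.character(sample_ids %||% rownames(counts) %||% sprintf("S%d", seq_len(n)))
  taxon_ids <- as.character(taxon_ids %||% colnames(counts) %||% sprintf("taxon%d", seq_len(m)))
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (anyDuplicated(taxon_ids)) stop("duplicate taxon ids")
  if (length(sample_ids) != n || length(taxon_ids) != m) stop("id length mismatch")
  rs <- unname(rowSums(counts))
  if (is.null(library_sizes)) {
    library_sizes <- rs
  } else {
    library_sizes <- unname(as.numeric(library_sizes))
    if (length(library_sizes) != n) stop("library_sizes length mismatch")
    if (any(library_sizes < rs - 1e-8))
      stop("library_sizes must be at least the row sums of the counts")
  }
  if (any(library_sizes <= 0))
    stop("library sizes must be positive; sample(s) with zero total: ",
         paste(sample_ids[library_sizes <= 0], collapse = ", "))
  dimnames(counts) <- list(sample_ids, taxon_ids)
  structure(list(counts = counts, sample_ids = sample_ids,
                 taxon_ids = taxon_ids, library_sizes = library_sizes),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d taxa\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("library sizes: median %s (range %s-%s)\n",
              format(stats::median(x$library_sizes)),
              format(min(x$library_sizes)), format(max(x$library_sizes))))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Read a count table from a tab-delimited file
#'
#' Expects a header row of taxon ids and a first column of sample ids;
#' remaining cells must be non-negative integers.
#'
#' @param path file path.
#' @param library_sizes optional vector overriding the row-sum library sizes.
#' @return a [count_table].
#' @export
read_count_table <- function(path, library_sizes = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expected sample-id column plus at least one taxon column")
  ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 2, as.numeric))),
                 arr.ind = TRUE)
    stop(sprintf("non-numeric count at row %d, column '%s'",
                 bad[1, 1], colnames(df)[-1][bad[1, 2]]))
  }
  count_table(mat, sample_ids = ids, taxon_ids = colnames(df)[-1],
              library_sizes = library_sizes)
}

#' Write a count table to a tab-delimited file
#'
#' Inverse of [read_count_table()]: header row of taxon ids, first column
#' `sample_id`.
#'
#' @param x a [count_table].
#' @param path file path.
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "count_table"))
  df <- data.frame(sample_id = x$sample_ids, x$counts,
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample covariate table
#'
#' Tab-delimited with a `sample_id` column; character columns are converted to
#' factors (levels in order of first appearance, so a file written by
#' [write_covariates()] round-trips with stable coding).
#'
#' @param path file path.
#' @return a data.frame.
#' @export
read_covariates <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("covariate table needs a sample_id column")
  df$sample_id <- as.character(df$sample_id)
  for (nm in setdiff(names(df), "sample_id"))
    if (is.character(df[[nm]])) df[[nm]] <- factor(df[[nm]], levels = unique(df[[nm]]))
  df
}

#' @rdname read_covariates
#' @param x data.frame with a `sample_id` column.
#' @export
write_covariates <- function(x, path) {
  stopifnot("sample_id" %in% names(x))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
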