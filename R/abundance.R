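#' Validate a sample-by-taxon abundance matrix
#'
#' The package's universal currency is a numeric matrix with samples as rows
#' and taxa as columns, row and column names set to unique sample and taxon
#' ids, and no negative or missing entries. Counts and relative abundances
#' share the representation; functions that need counts (e.g. [fit_ncm()])
#' say so.
#'
#' @param x numeric matrix, samples as rows, taxa as columns.
#' @param what label used in error messages.
#' @return `x`, invisibly, after validation.
#' @export
validate_abundance <- function(x, what = "abundance table") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix (samples x taxa)", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(what, " must have sample ids as rownames and taxon ids as colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(x)))
    stop(what, ": duplicate sample ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop(what, ": duplicate taxon ids: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "),
         call. = FALSE)
  bad <- which(is.na(x) | x < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(what, ": negative or missing value at sample '",
         rownames(x)[bad[1, 1]], "', taxon '", colnames(x)[bad[1, 2]], "'",
         call. = FALSE)
  }
  invisible(x)
}

#' Total-sum scaling to relative abundances
#'
#' Normalisation is always an explicit transform in this package, never
#' implicit on read: the neutral model needs counts to set the community
#' size, while diversity statistics accept either. All-zero samples are
#' left at zero.
#'
#' @param x abundance matrix (samples x taxa).
#' @return matrix of the same shape whose non-zero rows sum to 1.
#' @export
relative_abundance <- function(x) {
  validate_abundance(x)
  tot <- rowSums(x)
  tot[tot == 0] <- 1
  sweep(x, 1, tot, "/")
}

#' Read a TSV abundance table
#'
#' Expects a header row and ids in the first column. Files with taxa as rows
#' (the common QIIME-style export) are transposed on read via the
#' `orientation` flag; values are validated but never normalised.
#'
#' @param path TSV file path.
#' @param orientation `"samples"` if rows are samples (default) or `"taxa"`
#'   if rows are taxa.
#' @return validated abundance matrix, samples as rows.
#' @export
read_abundance_table <- function(path, orientation = c("samples", "taxa")) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("abundance table needs an id column plus data columns")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (orientation == "taxa") m <- t(m)
  validate_abundance(m, what = paste0("abundance table '", path, "'"))
  m
}

#' Write a TSV abundance table
#'
#' Samples as rows, first column `sample_id`; the exact inverse of
#' [read_abundance_table()] with `orientation = "samples"`.
#'
#' @param x abundance matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(x, path) {
  validate_abundance(x)
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' TSV with sample ids in the first column; remaining columns (typically
#' `group`, `timepoint`, `replicate`) are returned as-is.
#'
#' @param path TSV file path.
#' @return data.frame with rownames set to sample ids.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate sample ids in metadata")
  out <- df[, -1, drop = FALSE]
  rownames(out) <- ids
  out
}

#' @rdname read_metadata
#' @param meta metadata data.frame as returned by [read_metadata()].
#' @export
write_metadata <- function(meta, path) {
  df <- data.frame(sample_id = rownames(meta), meta, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
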