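#' Construct an ASV count table
#'
#' An `asv_table` stores non-negative integer counts for amplicon sequence
#' variants (ASVs) observed in a set of samples.  The matrix is always held
#' in samples-by-ASVs orientation with unique row (sample) and column (ASV)
#' identifiers; every downstream stage of the pipeline consumes this object.
#'
#' @param counts Numeric matrix of non-negative integers with sample IDs as
#'   row names and ASV IDs as column names.
#' @return An object of class `asv_table` wrapping the validated integer
#'   matrix.
#' @examples
#' m <- matrix(c(3L, 1L, 0L, 2L), 2, 2,
#'             dimnames = list(c("S1", "S2"), c("ASV1", "ASV2")))
#' asv_table(m)
#' @export
asv_table <- function(counts) {
  if (!is.matrix(counts)) stop_format("'counts' must be a matrix")
  if (nrow(counts) < 1L || ncol(counts) < 1L) {
    stop_format("ASV table must contain at least one sample and one ASV")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_format("ASV table requires sample IDs (rows) and ASV IDs (columns)")
  }
  if (anyDuplicated(rownames(counts))) stop_format("duplicate sample IDs")
  if (anyDuplicated(colnames(counts))) stop_format("duplicate ASV IDs")
  if (!is.numeric(counts)) stop_format("counts must be numeric")
  if (anyNA(counts)) stop_format("counts must not contain missing values")
  if (any(counts < 0)) stop_format("counts must be non-negative")
  if (any(counts != round(counts))) {
    stop_format("counts must be integers; relative abundances are not accepted")
  }
  storage.mode(counts) <- "integer"
  structure(list(counts = counts), class = "asv_table")
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf(
    "ASV table: %d samples x %d ASVs (%d total reads)\n",
    nrow(x$counts), ncol(x$counts), sum(x$counts)
  ))
  invisible(x)
}

#' @rdname asv_table
#' @param x An `asv_table`.
#' @export
sample_ids <- function(x) rownames(x$counts)

#' @rdname asv_table
#' @export
asv_ids <- function(x) colnames(x$counts)

#' @rdname asv_table
#' @export
n_samples <- function(x) nrow(x$counts)

#' @rdname asv_table
#' @export
n_asvs <- function(x) ncol(x$counts)

#' Presence/absence view of an ASV table
#'
#' @param x An `asv_table`.
#' @return Logical samples-by-ASVs matrix; `TRUE` where the count is > 0.
#' @export
presence_matrix <- function(x) {
  x$counts > 0L
}

subset_asv_table <- function(x, samples = NULL, asvs = NULL) {
  counts <- x$counts
  if (!is.null(samples)) counts <- counts[samples, , drop = FALSE]
  if (!is.null(asvs)) counts <- counts[, asvs, drop = FALSE]
  if (nrow(counts) == 0L) stop_empty("no samples left in ASV table")
  if (ncol(counts) == 0L) stop_empty("no ASVs left in ASV table")
  asv_table(counts)
}

#' Read an ASV count table from a tab-separated file
#'
#' The file must have one header row and one leading ID column; the body is
#' integer counts.  Tables stored with ASVs as rows are transposed on read so
#' the returned object is always samples-by-ASVs.
#'
#' @param path Path to a TSV file.
#' @param orientation Either `"samples_as_rows"` (default) or
#'   `"asvs_as_rows"` describing the file layout.
#' @return An [asv_table].
#' @export
read_asv_table <- function(path, orientation = c("samples_as_rows", "asvs_as_rows")) {
  orientation <- match.arg(orientation)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "", check.names = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0L || ncol(df) < 2L) stop_format("empty ASV table file")
  ids <- df[[1L]]
  if (anyDuplicated(ids)) stop_format("duplicate row IDs in ASV table file")
  if (anyDuplicated(colnames(df)[-1L])) {
    stop_format("duplicate column IDs in ASV table file")
  }
  body <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow(body), ncol(body)))
  if (anyNA(num)) stop_format("non-numeric cell in ASV table file")
  dimnames(num) <- list(ids, colnames(df)[-1L])
  if (orientation == "asvs_as_rows") num <- t(num)
  asv_table(num)
}

#' Write an ASV count table as TSV
#'
#' @param x An [asv_table].
#' @param path Output file path.
#' @param orientation File layout to write, as in [read_asv_table()].
#' @return `path`, invisibly.
#' @export
write_asv_table <- function(x, path, orientation = c("samples_as_rows", "asvs_as_rows")) {
  orientation <- match.arg(orientation)
  m <- x$counts
  id_col <- "sample_id"
  if (orientation == "asvs_as_rows") {
    m <- t(m)
    id_col <- "asv_id"
  }
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove shallow samples from an ASV table
#'
#' Samples whose total read count falls below `min_reads` are dropped; the
#' conventional threshold excludes samples with fewer than 1,000 sequences.
#' The ASV set is unchanged.  The IDs of removed samples are attached as the
#' `"removed_samples"` attribute of the result.
#'
#' @param table An [asv_table].
#' @param min_reads Minimum total reads a sample must have to be retained
#'   (strictly-less-than rule: a sample with exactly `min_reads` reads stays).
#' @return Filtered [asv_table] with attribute `removed_samples`.
#' @export
filter_sample_depth <- function(table, min_reads = 1000L) {
  if (!is.numeric(min_reads) || length(min_reads) != 1L || min_reads < 1) {
    stop_param("'min_reads' must be a positive integer")
  }
  depth <- rowSums(table$counts)
  keep <- depth >= min_reads
  if (!any(keep)) stop_empty("all samples fall below the read-depth threshold")
  out <- subset_asv_table(table, samples = which(keep))
  attr(out, "removed_samples") <- rownames(table$counts)[!keep]
  out
}

#' Remove rare ASVs by prevalence
#'
#' Retains ASVs detected (count > 0) in strictly more than `min_fraction` of
#' the samples.  With the default of 0.01 an ASV present in exactly 1% of
#' samples is removed, matching a "more than 1% of the samples" rule.  The
#' sample set is unchanged.
#'
#' @param table An [asv_table].
#' @param min_fraction Presence-fraction threshold in `[0, 1)`.
#' @return Filtered [asv_table] with attribute `removed_asvs`.
#' @export
filter_prevalence <- function(table, min_fraction = 0.01) {
  if (!is.numeric(min_fraction) || length(min_fraction) != 1L ||
      min_fraction < 0 || min_fraction >= 1) {
    stop_param("'min_fraction' must be in [0, 1)")
  }
  prev <- colMeans(table$counts > 0L)
  keep <- prev > min_fraction
  if (!any(keep)) stop_empty("all ASVs fall below the prevalence threshold")
  out <- subset_asv_table(table, asvs = which(keep))
  attr(out, "removed_asvs") <- colnames(table$counts)[!keep]
  out
}
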