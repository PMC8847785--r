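#' Read sample metadata from a tab-separated file
#'
#' The file must contain the columns `sample_id`, `population` and `source`;
#' `timepoint` (days since arrival in the common garden) and `tank` are
#' optional.  Extra columns (as in QIIME2-style sample metadata) are ignored.
#' Field samples have no common-garden timepoint or tank: these are stored as
#' `NA` sentinels, never as 0, because day 0 does not exist in a design whose
#' first garden timepoint is 24 h.
#'
#' @param path Path to a TSV file.
#' @return A validated `data.frame` with columns `sample_id`, `population`,
#'   `source`, `timepoint`, `tank`.
#' @export
read_metadata <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "", check.names = FALSE,
                          colClasses = "character")
  required <- c("sample_id", "population", "source")
  missing_cols <- setdiff(required, colnames(df))
  if (length(missing_cols) > 0L) {
    stop_format(paste0("metadata is missing required column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  if (!"timepoint" %in% colnames(df)) df$timepoint <- NA_character_
  if (!"tank" %in% colnames(df)) df$tank <- NA_character_
  tp <- df$timepoint
  tp[tp %in% c("", "NA", "not applicable")] <- NA_character_
  timepoint <- suppressWarnings(as.numeric(tp))
  if (any(!is.na(tp) & is.na(timepoint))) {
    stop_format("non-numeric timepoint in metadata")
  }
  tank <- df$tank
  tank[tank %in% c("", "NA", "not applicable")] <- NA_character_
  meta <- data.frame(
    sample_id = df$sample_id,
    population = df$population,
    source = df$source,
    timepoint = timepoint,
    tank = tank,
    stringsAsFactors = FALSE
  )
  validate_metadata(meta)
}

#' Validate a sample metadata table
#'
#' Checks the invariants of the metadata contract: unique sample IDs,
#' non-empty population labels, `source` restricted to `field` /
#' `common_garden`, field samples carrying the `NA` timepoint sentinel and
#' common-garden samples carrying a non-negative timepoint in days.
#'
#' @param meta A `data.frame` with columns `sample_id`, `population`,
#'   `source`, `timepoint`, `tank`.
#' @return The validated `data.frame`, invisibly unchanged.
#' @export
validate_metadata <- function(meta) {
  needed <- c("sample_id", "population", "source", "timepoint", "tank")
  missing_cols <- setdiff(needed, colnames(meta))
  if (length(missing_cols) > 0L) {
    stop_format(paste0("metadata is missing column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(meta$sample_id)) stop_format("duplicate sample IDs in metadata")
  if (any(is.na(meta$population) | meta$population == "")) {
    stop_format("empty population label in metadata")
  }
  bad_source <- setdiff(unique(meta$source), c("field", "common_garden"))
  if (length(bad_source) > 0L) {
    stop_format(paste0("unknown source value(s): ",
                       paste(bad_source, collapse = ", "),
                       " (must be 'field' or 'common_garden')"))
  }
  is_field <- meta$source == "field"
  if (any(is_field & !is.na(meta$timepoint))) {
    stop_format("field samples must carry the NA timepoint sentinel")
  }
  if (any(!is_field & (is.na(meta$timepoint) | meta$timepoint < 0))) {
    stop_format("common-garden samples require a timepoint >= 0 days")
  }
  meta
}

#' Write sample metadata as TSV
#'
#' @param meta Metadata `data.frame` as returned by [read_metadata()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  out <- meta
  out$timepoint <- ifelse(is.na(out$timepoint), "not applicable",
                          format(out$timepoint, trim = TRUE, scientific = FALSE))
  out$tank <- ifelse(is.na(out$tank), "not applicable", out$tank)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select sample IDs by metadata attributes
#'
#' Convenience filter used to build the contrasts between common-garden and
#' field samples: each non-NULL argument restricts the selection.
#'
#' @param meta Metadata `data.frame`.
#' @param source Optional source label(s) to keep.
#' @param population Optional population label(s) to keep.
#' @param timepoint Optional timepoint(s) in days to keep.
#' @return Character vector of matching sample IDs.
#' @export
select_samples <- function(meta, source = NULL, population = NULL, timepoint = NULL) {
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(source)) keep <- keep & meta$source %in% source
  if (!is.null(population)) keep <- keep & meta$population %in% population
  if (!is.null(timepoint)) keep <- keep & !is.na(meta$timepoint) &
      meta$timepoint %in% timepoint
  meta$sample_id[keep]
}

#' Read a taxonomy table from a tab-separated file
#'
#' Expects an `asv_id` column followed by rank columns (domain through genus,
#' any suffix may be absent).  Only the order rank is consumed downstream,
#' for order-level flexibility summaries.
#'
#' @param path Path to a TSV file.
#' @return A `data.frame` with `asv_id` and the rank columns found.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "", check.names = FALSE,
                          colClasses = "character")
  if (!"asv_id" %in% colnames(df)) stop_format("taxonomy requires an 'asv_id' column")
  if (anyDuplicated(df$asv_id)) stop_format("duplicate ASV IDs in taxonomy")
  df
}
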