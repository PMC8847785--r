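#' Sorensen-Dice dissimilarity matrix
#'
#' Computes pairwise Sorensen-Dice dissimilarities between samples of an ASV
#' table.  For samples i and j let a be the number of ASVs present (count >
#' 0) in both, b the number present only in i and c the number present only
#' in j; then
#' \deqn{D(i,j) = 1 - \frac{2a}{2a + b + c}.}
#' The index is binary: abundances beyond presence/absence do not enter.  A
#' quantitative variant (1 - 2*sum(min)/sum(x + y) on counts) is available
#' but is not the default, since the named index is a presence/absence
#' measure.
#'
#' Two samples sharing no ASVs get D = 1.  A sample with no ASVs at all has
#' no defined dissimilarity to anything and raises an error naming it.
#'
#' @param table An [asv_table].
#' @param binary Use presence/absence (default `TRUE`).
#' @return A symmetric numeric matrix with zero diagonal, entries in
#'   `[0, 1]`, and sample IDs as dimnames.
#' @export
sorensen_dice_matrix <- function(table, binary = TRUE) {
  counts <- table$counts
  empty <- rowSums(counts) == 0L
  if (any(empty)) {
    stop_param(paste0("Sorensen-Dice is undefined for all-zero sample(s): ",
                      paste(rownames(counts)[empty], collapse = ", ")))
  }
  if (binary) {
    p <- (counts > 0L) * 1
    shared <- tcrossprod(p)              # a for every pair
    size <- rowSums(p)                   # a + b per sample
    denom <- outer(size, size, "+")      # 2a + b + c
    d <- 1 - 2 * shared / denom
  } else {
    x <- counts
    n <- nrow(x)
    d <- matrix(0, n, n)
    tot <- rowSums(x)
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        mins <- sum(pmin(x[i, ], x[j, ]))
        d[i, j] <- d[j, i] <- 1 - 2 * mins / (tot[i] + tot[j])
      }
    }
    dimnames(d) <- list(rownames(x), rownames(x))
  }
  diag(d) <- 0
  d[d < 0] <- 0
  d[d > 1] <- 1
  dimnames(d) <- list(rownames(counts), rownames(counts))
  d
}

#' Write / read a labeled square distance matrix
#'
#' The on-disk dialect is a square TSV whose first column and header carry
#' matching sample IDs.
#'
#' @param d Symmetric numeric matrix with sample IDs as dimnames.
#' @param path File path.
#' @return `path` (write) or the matrix (read).
#' @export
write_distance_matrix <- function(d, path) {
  df <- data.frame(rownames(d), d, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1L] <- "sample_id"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "", check.names = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!identical(colnames(m), ids)) {
    stop_format("distance matrix row and column IDs do not match")
  }
  storage.mode(m) <- "double"
  dimnames(m) <- list(ids, ids)
  if (max(abs(m - t(m))) > 1e-12) stop_format("distance matrix is not symmetric")
  m
}

resolve_selection <- function(sel, meta) {
  ids <- if (is.function(sel)) {
    meta$sample_id[sel(meta)]
  } else if (is.logical(sel)) {
    meta$sample_id[sel]
  } else {
    as.character(sel)
  }
  unknown <- setdiff(ids, meta$sample_id)
  if (length(unknown) > 0L) {
    stop_param(paste0("selection references unknown sample(s): ",
                      paste(unknown, collapse = ", ")))
  }
  ids
}

#' Extract labeled pairwise dissimilarities between two sample selections
#'
#' Enumerates every unordered pair with one member matching `set_a` and one
#' matching `set_b` (self-pairs excluded, each pair counted once) and labels
#' it `within_population` or `between_population` by population equality.
#' This supports the study's contrasts: common-garden versus field samples
#' across all timepoints, at the final timepoint only, and per population
#' over time.
#'
#' @param dist Symmetric distance matrix with sample IDs as dimnames.
#' @param meta Metadata `data.frame` covering all selected samples.
#' @param set_a,set_b Sample selections: a character vector of sample IDs, a
#'   logical vector over metadata rows, or a predicate function taking the
#'   metadata `data.frame` and returning a logical vector.
#' @return A `data.frame` with one row per pair: `sample_a`, `sample_b`,
#'   `dissimilarity`, `comparison_class`, `population_a`, `population_b`,
#'   and `garden_timepoint` (the timepoint of the pair's common-garden
#'   member, or of `sample_a` when both are from the garden; `NA` when
#'   neither is).
#' @export
pairwise_comparisons <- function(dist, meta, set_a, set_b) {
  ids_a <- resolve_selection(set_a, meta)
  ids_b <- resolve_selection(set_b, meta)
  if (length(ids_a) == 0L || length(ids_b) == 0L) {
    stop_empty("empty sample selection for pairwise comparisons")
  }
  missing_ids <- setdiff(c(ids_a, ids_b), rownames(dist))
  if (length(missing_ids) > 0L) {
    stop_param(paste0("samples absent from distance matrix: ",
                      paste(missing_ids, collapse = ", ")))
  }
  grid <- expand.grid(sample_a = ids_a, sample_b = ids_b,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$sample_a != grid$sample_b, , drop = FALSE]
  # deduplicate unordered pairs
  key <- ifelse(grid$sample_a < grid$sample_b,
                paste(grid$sample_a, grid$sample_b),
                paste(grid$sample_b, grid$sample_a))
  grid <- grid[!duplicated(key), , drop = FALSE]
  if (nrow(grid) == 0L) stop_empty("no pairs left after removing self-pairs")

  rownames(meta) <- meta$sample_id
  pop_a <- meta[grid$sample_a, "population"]
  pop_b <- meta[grid$sample_b, "population"]
  src_a <- meta[grid$sample_a, "source"]
  src_b <- meta[grid$sample_b, "source"]
  tp_a <- meta[grid$sample_a, "timepoint"]
  tp_b <- meta[grid$sample_b, "timepoint"]
  garden_timepoint <- ifelse(src_a == "common_garden", tp_a,
                             ifelse(src_b == "common_garden", tp_b, NA_real_))
  data.frame(
    sample_a = grid$sample_a,
    sample_b = grid$sample_b,
    dissimilarity = dist[cbind(grid$sample_a, grid$sample_b)],
    comparison_class = ifelse(pop_a == pop_b, "within_population",
                              "between_population"),
    population_a = pop_a,
    population_b = pop_b,
    garden_timepoint = garden_timepoint,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Write a pairwise comparison set as long-format TSV
#'
#' @param pairs `data.frame` from [pairwise_comparisons()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pairwise_comparisons <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
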