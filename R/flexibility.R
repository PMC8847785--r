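# Per-ASV host-flexibility scoring: the module that separates resident
# (population-restricted) from transient (environmentally exchanged)
# microbiome members.

choose2 <- function(k) k * (k - 1) / 2

# Vectorized sharing components for every ASV at once.
# For each ASV, over all unordered sample pairs where the ASV is present in
# at least one member, a pair scores 1 when present in both and 0 when
# present in exactly one; double-absence pairs are excluded (the per-pair
# binary Sorensen similarity is undefined there).  s_within averages
# same-population pairs, s_between different-population pairs.
sharing_components <- function(table, meta) {
  rownames(meta) <- meta$sample_id
  missing_ids <- setdiff(sample_ids(table), meta$sample_id)
  if (length(missing_ids) > 0L) {
    stop_param(paste0("metadata missing sample(s): ",
                      paste(missing_ids, collapse = ", ")))
  }
  pop <- meta[sample_ids(table), "population"]
  if (length(unique(pop)) < 2L) {
    stop_design("flexibility scores require at least two populations")
  }
  p <- presence_matrix(table) * 1
  n <- nrow(p)
  n_g <- as.vector(table(pop))
  ind <- outer(pop, names(table(pop)), "==") * 1      # samples x groups
  k_g <- crossprod(ind, p)                            # groups x ASVs

  within_both <- colSums(choose2(k_g))
  within_either <- colSums(choose2(n_g) - choose2(n_g - k_g))
  k_tot <- colSums(p)
  total_both <- choose2(k_tot)
  total_either <- choose2(n) - choose2(n - k_tot)
  between_both <- total_both - within_both
  between_either <- total_either - within_either

  data.frame(
    asv_id = asv_ids(table),
    s_within = ifelse(within_either > 0, within_both / within_either, NA_real_),
    s_between = ifelse(between_either > 0, between_both / between_either, NA_real_),
    n_within_pairs = as.integer(within_either),
    n_between_pairs = as.integer(between_either),
    prevalence = k_tot / n,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Within- and between-population sharing of a single ASV
#'
#' Over all unordered sample pairs in which the ASV is present in at least
#' one member, a pair scores 1 when the ASV is present in both members and
#' 0 when present in exactly one; pairs where both members lack the ASV are
#' excluded.  `s_within` is the mean score over same-population pairs and
#' `s_between` over different-population pairs.
#'
#' @param table An [asv_table].
#' @param meta Metadata `data.frame` covering all samples.
#' @param asv A single ASV ID present in the table.
#' @return A list with `s_within`, `s_between`, `n_within_pairs`,
#'   `n_between_pairs` (`NA` components when an ASV has no eligible pair in
#'   a class).
#' @export
per_asv_sharing <- function(table, meta, asv) {
  if (!asv %in% asv_ids(table)) {
    stop_param(paste0("unknown ASV: ", asv))
  }
  comp <- sharing_components(table, meta)
  row <- comp[comp$asv_id == asv, ]
  as.list(row[c("s_within", "s_between", "n_within_pairs", "n_between_pairs")])
}

#' Flexibility scores for all ASVs
#'
#' The flexibility score (FS) of an ASV contrasts how often it is shared by
#' individuals of the same population versus individuals of different
#' populations.  In the default `"sharing"` mode
#' \deqn{FS = \frac{s_{within} + smoothing}{s_{between} + smoothing}}
#' so FS > 1 marks an ASV restricted to specific populations (a resident
#' association with the host population), FS < 1 an ASV shared across
#' populations more than within (a transient, environmentally exchanged
#' association), and FS = 1 indifference to population.  The alternative
#' `"dissimilarity"` mode uses the per-pair dissimilarity complement,
#' \eqn{(1 - s_{within}) / (1 - s_{between})}, whose orientation is
#' reciprocal (residents score below 1); the residency call is flipped
#' accordingly so the two modes classify identically.
#'
#' ASVs are first filtered to those present in strictly more than
#' `min_prevalence` of the samples.  With `smoothing = 0` an ASV never
#' shared between populations but shared within gets FS = +Inf and still
#' classifies as resident; an ASV with no eligible pair in either class, or
#' zero sharing in both classes, has an undefined FS (`NA`) and an
#' `"undefined"` residency call.
#'
#' @inheritParams per_asv_sharing
#' @param min_prevalence Strict presence-fraction threshold (default 0.01).
#' @param smoothing Non-negative pseudo-count added to both sharing
#'   components (default 0, closest to the plain definition).
#' @param fs_mode `"sharing"` (default) or `"dissimilarity"`.
#' @return A `data.frame` of class `flexibility_table`: `asv_id`,
#'   `s_within`, `s_between`, `fs`, `n_within_pairs`, `n_between_pairs`,
#'   `residency` (resident/transient/neutral/undefined), `prevalence`.
#' @export
flexibility_scores <- function(table, meta, min_prevalence = 0.01,
                               smoothing = 0,
                               fs_mode = c("sharing", "dissimilarity")) {
  fs_mode <- match.arg(fs_mode)
  if (smoothing < 0) stop_param("'smoothing' must be non-negative")
  table <- filter_prevalence(table, min_prevalence)
  comp <- sharing_components(table, meta)

  if (fs_mode == "sharing") {
    num <- comp$s_within + smoothing
    den <- comp$s_between + smoothing
  } else {
    num <- (1 - comp$s_within) + smoothing
    den <- (1 - comp$s_between) + smoothing
  }
  fs <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, NA_real_))
  fs[is.na(comp$s_within) | is.na(comp$s_between)] <- NA_real_
  fs[is.nan(fs)] <- NA_real_

  resident_high <- fs_mode == "sharing"
  residency <- rep("undefined", length(fs))
  defined <- !is.na(fs)
  residency[defined & fs == 1] <- "neutral"
  residency[defined & fs > 1] <- if (resident_high) "resident" else "transient"
  residency[defined & fs < 1] <- if (resident_high) "transient" else "resident"

  out <- data.frame(
    asv_id = comp$asv_id,
    s_within = comp$s_within,
    s_between = comp$s_between,
    fs = fs,
    n_within_pairs = comp$n_within_pairs,
    n_between_pairs = comp$n_between_pairs,
    residency = residency,
    prevalence = comp$prevalence,
    stringsAsFactors = FALSE
  )
  class(out) <- c("flexibility_table", "data.frame")
  attr(out, "fs_mode") <- fs_mode
  attr(out, "smoothing") <- smoothing
  out
}

#' Select the top and bottom flexibility-score tails
#'
#' Tail size per side is `ceiling(fraction * n)` where n counts ASVs with a
#' defined (finite or infinite) FS.  Infinite FS ranks above every finite
#' value.  Ties at a tail boundary are broken by higher prevalence, then by
#' lexicographic ASV ID.
#'
#' @param fs_table A [flexibility_scores()] result.
#' @param fraction Tail fraction per side, in (0, 0.5).
#' @return A list with `fraction`, `top_asvs`, `bottom_asvs` (ordered from
#'   most extreme inward).
#' @export
select_tails <- function(fs_table, fraction = 0.01) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 0.5) {
    stop_param("'fraction' must lie strictly between 0 and 0.5")
  }
  ranked <- fs_table[!is.na(fs_table$fs), , drop = FALSE]
  n <- nrow(ranked)
  if (n == 0L) stop_empty("no ASVs with a defined flexibility score")
  k <- ceiling(fraction * n)
  top_ord <- order(-ranked$fs, -ranked$prevalence, ranked$asv_id)
  bottom_ord <- order(ranked$fs, -ranked$prevalence, ranked$asv_id)
  list(
    fraction = fraction,
    top_asvs = ranked$asv_id[top_ord][seq_len(k)],
    bottom_asvs = ranked$asv_id[bottom_ord][seq_len(k)]
  )
}

#' Order-level summary of flexibility scores
#'
#' Groups scored ASVs by their taxonomic order and summarises the FS
#' distribution per order: minimum, quartiles, maximum, count, and the
#' fraction of ASVs with FS > 1.  ASVs without an order label are grouped
#' under `"unclassified"`.
#'
#' @param fs_table A [flexibility_scores()] result.
#' @param taxonomy Taxonomy `data.frame` with `asv_id` and an `order`
#'   column.
#' @return A `data.frame` with one row per order.
#' @export
order_level_summary <- function(fs_table, taxonomy) {
  if (!"order" %in% colnames(taxonomy)) {
    stop_format("taxonomy must contain an 'order' column")
  }
  scored <- fs_table[!is.na(fs_table$fs), , drop = FALSE]
  ord <- taxonomy$order[match(scored$asv_id, taxonomy$asv_id)]
  ord[is.na(ord) | ord == ""] <- "unclassified"
  if (all(!scored$asv_id %in% taxonomy$asv_id)) {
    stop_empty("taxonomy covers none of the scored ASVs")
  }
  res <- lapply(split(scored$fs, ord), function(v) {
    q <- stats::quantile(v[is.finite(v)], c(0.25, 0.5, 0.75),
                         names = FALSE, type = 7)
    if (all(!is.finite(v))) q <- rep(Inf, 3L)
    data.frame(
      n = length(v),
      min = min(v),
      q1 = q[1L], median = q[2L], q3 = q[3L],
      max = max(v),
      fraction_fs_gt1 = mean(v > 1)
    )
  })
  out <- do.call(rbind, res)
  out <- cbind(data.frame(order = names(res), stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}

#' Write a flexibility table as TSV
#'
#' @param fs_table A [flexibility_scores()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_flexibility_table <- function(fs_table, path) {
  utils::write.table(as.data.frame(fs_table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
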