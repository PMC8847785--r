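#' Validate pipeline inputs
#'
#' Checks that every sample in the ASV table has metadata (fatal if not),
#' that at least two populations are present (fatal), that both field and
#' common-garden samples exist (fatal for the full pipeline, since every
#' contrast compares the two), and reports extra metadata rows as a
#' warning-level issue.
#'
#' @param table An [asv_table].
#' @param meta Metadata `data.frame`.
#' @return A list with `fatal` and `warnings`, each a character vector of
#'   issue descriptions (empty when clean).
#' @export
validate_inputs <- function(table, meta) {
  fatal <- character(0)
  warnings <- character(0)
  missing_meta <- setdiff(sample_ids(table), meta$sample_id)
  if (length(missing_meta) > 0L) {
    fatal <- c(fatal, paste0("samples without metadata: ",
                             paste(missing_meta, collapse = ", ")))
  }
  extra_meta <- setdiff(meta$sample_id, sample_ids(table))
  if (length(extra_meta) > 0L) {
    warnings <- c(warnings, paste0("metadata rows without samples: ",
                                   paste(extra_meta, collapse = ", ")))
  }
  covered <- meta[meta$sample_id %in% sample_ids(table), , drop = FALSE]
  if (length(unique(covered$population)) < 2L) {
    fatal <- c(fatal, "fewer than two populations")
  }
  if (!all(c("field", "common_garden") %in% covered$source)) {
    fatal <- c(fatal, "both field and common_garden samples are required")
  }
  list(fatal = fatal, warnings = warnings)
}

#' Run the full resident/transient analysis pipeline
#'
#' Executes the analysis chain in fixed order: sample-depth filter;
#' Sorensen-Dice dissimilarities on the field and common-garden strata
#' separately; PERMANOVA and dispersion homogeneity per stratum (is
#' community composition structured by population, and does that structure
#' persist in the shared environment?); the within- versus
#' between-population contrast of common-garden-vs-field dissimilarities by
#' rank-sum test, over all timepoints and at the final timepoint;
#' per-population divergence regression over time; and the flexibility-score
#' stage (prevalence filter, FS, dip test for bimodality, top/bottom tails,
#' and an order-level summary when taxonomy is supplied).  Field and garden
#' strata are never pooled in the PERMANOVA.  No multiple-testing
#' correction is applied across the report; all p-values are uncorrected.
#'
#' Permutation and bootstrap seeds are derived deterministically from
#' `seed` (stage index offsets), so the same inputs and seed yield a
#' byte-identical report.
#'
#' @param table An [asv_table] or path to one (TSV, samples as rows).
#' @param metadata Metadata `data.frame` or path to a metadata TSV.
#' @param taxonomy Optional taxonomy `data.frame` or TSV path.
#' @param out_dir Optional output directory; when given, every intermediate
#'   artifact (filtered table, distance matrix, pair tables, flexibility
#'   table, tails, and a one-row-per-test `tests_summary.tsv`) is written
#'   as TSV and the consolidated report as `report.json`.
#' @param min_reads Sample-depth threshold (default 1000).
#' @param min_prevalence Prevalence threshold for the FS stage only
#'   (default 0.01); beta-diversity stages use the unfiltered ASV set.
#' @param n_permutations Permutations for PERMANOVA and dispersion tests.
#' @param tail_fraction FS tail fraction per side (default 0.01).
#' @param dip_bootstrap Bootstrap replicates for the dip test.
#' @param seed Integer seed (mandatory).
#' @param run_flexibility Toggle for the FS stage.
#' @param run_beta Toggle for the beta-diversity / multivariate stage.
#' @return The report, a nested list (also written as JSON when `out_dir`
#'   is set).
#' @export
run_pipeline <- function(table, metadata, taxonomy = NULL, out_dir = NULL,
                         min_reads = 1000L, min_prevalence = 0.01,
                         n_permutations = 999L, tail_fraction = 0.01,
                         dip_bootstrap = 2000L, seed,
                         run_flexibility = TRUE, run_beta = TRUE) {
  if (missing(seed)) stop_param("'seed' is mandatory")
  if (is.character(table)) table <- read_asv_table(table)
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  if (is.character(taxonomy)) taxonomy <- read_taxonomy(taxonomy)
  metadata <- validate_metadata(metadata)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rt_stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
              "restrans_stage_error")
    })
  }
  emit <- function(fname, writer) {
    if (!is.null(out_dir)) writer(file.path(out_dir, fname))
  }
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  report <- list(
    config = list(min_reads = min_reads, min_prevalence = min_prevalence,
                  n_permutations = n_permutations,
                  tail_fraction = tail_fraction,
                  dip_bootstrap = dip_bootstrap, seed = seed),
    stages = list()
  )

  # -- validation ------------------------------------------------------
  issues <- stage("validate", {
    v <- validate_inputs(table, metadata)
    if (length(v$fatal) > 0L) {
      stop_param(paste(v$fatal, collapse = "; "))
    }
    v
  })
  report$warnings <- issues$warnings

  # -- depth filter ----------------------------------------------------
  filtered <- stage("depth_filter", filter_sample_depth(table, min_reads))
  removed <- attr(filtered, "removed_samples")
  report$stages$depth_filter <- list(
    samples_in = n_samples(table),
    samples_kept = n_samples(filtered),
    samples_removed = length(removed),
    removed_samples = as.list(removed)
  )
  meta <- metadata[match(sample_ids(filtered), metadata$sample_id), ,
                   drop = FALSE]
  emit("filtered_table.tsv", function(p) write_asv_table(filtered, p))

  if (run_beta) {
    # -- distances per stratum + pooled -------------------------------
    field_ids <- meta$sample_id[meta$source == "field"]
    garden_ids <- meta$sample_id[meta$source == "common_garden"]
    dist_all <- stage("distances", sorensen_dice_matrix(filtered))
    emit("distances.tsv", function(p) write_distance_matrix(dist_all, p))
    pop_of <- stats::setNames(meta$population, meta$sample_id)

    strata <- list(field = field_ids, common_garden = garden_ids)
    report$stages$permanova <- list()
    report$stages$dispersion <- list()
    offs <- 0L
    for (s in names(strata)) {
      ids <- strata[[s]]
      d_s <- dist_all[ids, ids, drop = FALSE]
      offs <- offs + 1L
      pr <- stage(paste0("permanova_", s),
                  permanova(d_s, pop_of[ids],
                            n_permutations = n_permutations,
                            seed = seed + offs))
      offs <- offs + 1L
      dr <- stage(paste0("dispersion_", s),
                  dispersion_test(d_s, pop_of[ids],
                                  n_permutations = n_permutations,
                                  seed = seed + offs))
      report$stages$permanova[[s]] <- unclass(pr)
      report$stages$dispersion[[s]] <- list(
        F_statistic = dr$F_statistic, p_value = dr$p_value,
        n_permutations = dr$n_permutations,
        group_dispersions = as.list(dr$group_dispersions)
      )
    }

    # -- garden vs field contrast -------------------------------------
    contrast <- stage("cg_vs_field_contrast", {
      pairs <- pairwise_comparisons(dist_all, meta,
                                    set_a = garden_ids, set_b = field_ids)
      emit("cg_vs_field_pairs.tsv",
           function(p) write_pairwise_comparisons(pairs, p))
      w <- pairs$dissimilarity[pairs$comparison_class == "within_population"]
      b <- pairs$dissimilarity[pairs$comparison_class == "between_population"]
      rs <- rank_sum_test(w, b)
      final_tp <- max(meta$timepoint, na.rm = TRUE)
      final_ids <- meta$sample_id[!is.na(meta$timepoint) &
                                    meta$timepoint == final_tp]
      pairs_final <- pairwise_comparisons(dist_all, meta,
                                          set_a = final_ids, set_b = field_ids)
      wf <- pairs_final$dissimilarity[
        pairs_final$comparison_class == "within_population"]
      bf <- pairs_final$dissimilarity[
        pairs_final$comparison_class == "between_population"]
      rs_final <- rank_sum_test(wf, bf)
      list(pairs = pairs,
           all_timepoints = list(
             mean_within = mean(w), mean_between = mean(b),
             n_within = length(w), n_between = length(b),
             U = rs$statistic_U, p_value = rs$p_value, method = rs$method),
           final_timepoint = list(
             timepoint = final_tp,
             mean_within = mean(wf), mean_between = mean(bf),
             n_within = length(wf), n_between = length(bf),
             U = rs_final$statistic_U, p_value = rs_final$p_value,
             method = rs_final$method))
    })
    report$stages$cg_vs_field <- contrast[c("all_timepoints", "final_timepoint")]

    # -- divergence over time -----------------------------------------
    divergence <- stage("divergence", {
      within <- contrast$pairs[
        contrast$pairs$comparison_class == "within_population", , drop = FALSE]
      divergence_regression(within, per_population = TRUE)
    })
    emit("divergence.tsv", function(p)
      utils::write.table(divergence, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
    report$stages$divergence <- lapply(
      split(divergence, seq_len(nrow(divergence))),
      function(r) as.list(r)
    )
    names(report$stages$divergence) <- divergence$population
  }

  if (run_flexibility) {
    flex <- stage("flexibility", {
      fs_tab <- flexibility_scores(filtered, meta,
                                   min_prevalence = min_prevalence)
      emit("flexibility_table.tsv",
           function(p) write_flexibility_table(fs_tab, p))
      dip <- dip_test(fs_tab$fs, n_bootstrap = dip_bootstrap,
                      seed = seed + 100L)
      tails <- select_tails(fs_tab, tail_fraction)
      emit("fs_tails.tsv", function(p) {
        utils::write.table(
          data.frame(
            tail = rep(c("top", "bottom"),
                       c(length(tails$top_asvs), length(tails$bottom_asvs))),
            asv_id = c(tails$top_asvs, tails$bottom_asvs)),
          p, sep = "\t", quote = FALSE, row.names = FALSE)
      })
      order_summary <- NULL
      if (!is.null(taxonomy)) {
        order_summary <- order_level_summary(fs_tab, taxonomy)
        emit("order_summary.tsv", function(p)
          utils::write.table(order_summary, p, sep = "\t", quote = FALSE,
                             row.names = FALSE))
      }
      list(fs_tab = fs_tab, dip = dip, tails = tails,
           order_summary = order_summary)
    })
    res <- table(flex$fs_tab$residency)
    report$stages$flexibility <- list(
      n_scored = sum(!is.na(flex$fs_tab$fs)),
      n_resident = unname(res["resident"] %||% 0L),
      n_transient = unname(res["transient"] %||% 0L),
      n_neutral = unname(res["neutral"] %||% 0L),
      n_undefined = unname(res["undefined"] %||% 0L),
      n_infinite = sum(is.infinite(flex$fs_tab$fs)),
      dip = unclass(flex$dip),
      top_asvs = as.list(flex$tails$top_asvs),
      bottom_asvs = as.list(flex$tails$bottom_asvs)
    )
  }

  if (!is.null(out_dir)) {
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    write_test_summary(report, file.path(out_dir, "tests_summary.tsv"))
  }
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

# One row per hypothesis test in the report (statistic + uncorrected p).
write_test_summary <- function(report, path) {
  rows <- list()
  add <- function(test, statistic, p_value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      test = test, statistic = statistic, p_value = p_value,
      stringsAsFactors = FALSE)
  }
  for (s in names(report$stages$permanova)) {
    add(paste0("permanova_", s), report$stages$permanova[[s]]$pseudo_F,
        report$stages$permanova[[s]]$p_value)
    add(paste0("dispersion_", s), report$stages$dispersion[[s]]$F_statistic,
        report$stages$dispersion[[s]]$p_value)
  }
  if (!is.null(report$stages$cg_vs_field)) {
    add("wilcoxon_within_vs_between_all",
        report$stages$cg_vs_field$all_timepoints$U,
        report$stages$cg_vs_field$all_timepoints$p_value)
    add("wilcoxon_within_vs_between_final",
        report$stages$cg_vs_field$final_timepoint$U,
        report$stages$cg_vs_field$final_timepoint$p_value)
  }
  for (pop in names(report$stages$divergence)) {
    add(paste0("divergence_slope_", pop),
        report$stages$divergence[[pop]]$slope,
        report$stages$divergence[[pop]]$slope_p_value)
  }
  if (!is.null(report$stages$flexibility)) {
    add("dip_unimodality", report$stages$flexibility$dip$dip_statistic,
        report$stages$flexibility$dip$p_value)
  }
  if (length(rows) > 0L) {
    utils::write.table(do.call(rbind, rows), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
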