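small_config <- function(...) {
  generator_config(n_populations = 3, n_field_per_pop = 3,
                   garden_timepoints_days = c(1, 7, 21),
                   n_garden_per_pop_per_timepoint = 2,
                   n_resident_asvs_per_pop = 10, n_shared_core_asvs = 20,
                   n_transient_pool_asvs = 30, mean_depth = 5000,
                   transient_pulses_per_asv = 1, ...)
}

test_that("the default design yields the documented sample layout", {
  d <- generate_dataset(generator_config())
  expect_identical(n_samples(d$table), 222L)       # 6*5 field + 6*8*4 garden
  expect_identical(sum(d$metadata$source == "field"), 30L)
  expect_identical(sum(d$metadata$source == "common_garden"), 192L)
  expect_identical(length(unique(d$metadata$population)), 6L)
  expect_true(all(is.na(d$metadata$timepoint[d$metadata$source == "field"])))
  expect_identical(sort(unique(stats::na.omit(d$metadata$timepoint))),
                   c(1, 2, 7, 14, 21, 28, 35, 42))
  # every ASV labeled exactly once in the truth
  expect_identical(sort(d$truth$asv_id), sort(asv_ids(d$table)))
  expect_identical(nrow(d$truth), 6L * 30L + 120L + 200L)
})

test_that("generation is deterministic given the seed", {
  cfg <- small_config(seed = 33)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$table$counts, d2$table$counts)
  d3 <- generate_dataset(small_config(seed = 34))
  expect_false(identical(d1$table$counts, d3$table$counts))
})

test_that("degenerate probabilities make residents perfectly restricted", {
  cfg <- small_config(p_leak = 0, p_present_resident = 1, p_shallow = 0,
                      seed = 5)
  d <- generate_dataset(cfg)
  pres <- presence_matrix(d$table)
  for (j in which(d$truth$class == "resident")) {
    home <- d$metadata$population == d$truth$home_population[j]
    expect_true(all(pres[home, j]))
    expect_false(any(pres[!home, j]))
  }
})

test_that("realized presence frequencies track configured probabilities", {
  cfg <- generator_config(seed = 6, p_shallow = 0)
  d <- generate_dataset(cfg)
  pres <- presence_matrix(d$table)
  meta <- d$metadata

  # residents at home: Bernoulli(0.9) over home samples x ASVs
  res_idx <- which(d$truth$class == "resident")
  n_draw <- 0; n_hit <- 0
  for (j in res_idx) {
    home <- meta$population == d$truth$home_population[j]
    n_draw <- n_draw + sum(home)
    n_hit <- n_hit + sum(pres[home, j])
  }
  se <- sqrt(0.9 * 0.1 / n_draw)
  expect_lt(abs(n_hit / n_draw - 0.9), 3 * se)

  # core everywhere: Bernoulli(0.8)
  core_idx <- which(d$truth$class == "core")
  p_hat <- mean(pres[, core_idx])
  se_c <- sqrt(0.8 * 0.2 / (nrow(pres) * length(core_idx)))
  expect_lt(abs(p_hat - 0.8), 3 * se_c)

  # transients in the field: Bernoulli(base = 0.05)
  tr_idx <- which(d$truth$class == "transient")
  fld <- meta$source == "field"
  p_tr <- mean(pres[fld, tr_idx])
  se_t <- sqrt(0.05 * 0.95 / (sum(fld) * length(tr_idx)))
  expect_lt(abs(p_tr - 0.05), 3 * se_t)
})

test_that("sequencing depth model produces shallow samples to filter", {
  cfg <- generator_config(seed = 7, p_shallow = 0.1)
  d <- generate_dataset(cfg)
  depth <- rowSums(d$table$counts)
  expect_gt(sum(depth < 1000), 0)
  filt <- filter_sample_depth(d$table)
  expect_identical(n_samples(filt) + length(attr(filt, "removed_samples")),
                   n_samples(d$table))
})

test_that("faster exchange steepens garden-vs-field divergence; zero rate flattens it", {
  cfg <- generator_config(seed = 8, exchange_rate_per_day = c(0, 0.3),
                          p_shallow = 0)
  d <- generate_dataset(cfg)
  dist <- sorensen_dice_matrix(d$table)
  garden <- select_samples(d$metadata, source = "common_garden")
  field <- select_samples(d$metadata, source = "field")
  pairs <- pairwise_comparisons(dist, d$metadata, garden, field)
  within <- pairs[pairs$comparison_class == "within_population", ]
  fits <- divergence_regression(within, per_population = TRUE)
  lam <- stats::setNames(d$config$exchange_rate_per_day,
                         unique(d$metadata$population))
  slow <- fits$slope[fits$population %in% names(lam)[lam == 0]]
  fast <- fits$slope[fits$population %in% names(lam)[lam > 0]]
  expect_gt(min(fast), max(slow))
  expect_gt(mean(fast), 0)
  # lambda = 0 populations: slope statistically indistinguishable from 0
  slow_p <- fits$slope_p_value[fits$population %in% names(lam)[lam == 0]]
  expect_gt(min(slow_p), 0.05)
})

test_that("the null generator removes population structure", {
  cfg <- small_config(seed = 9)
  d <- generate_null_dataset(cfg)
  expect_true(all(d$truth$class == "null"))
  # a PERMANOVA on null data should not find structure at alpha = 0.01
  dist <- sorensen_dice_matrix(d$table)
  pops <- stats::setNames(d$metadata$population, d$metadata$sample_id)
  res <- permanova(dist, pops[rownames(dist)], n_permutations = 199, seed = 1)
  expect_gt(res$p_value, 0.01)
})

test_that("taxonomy contains pure and mixed synthetic orders", {
  d <- generate_dataset(generator_config(seed = 10))
  tax_class <- merge(d$taxonomy, d$truth, by = "asv_id")
  by_order <- split(tax_class$class.y, tax_class$order)
  n_classes <- vapply(by_order, function(v) length(unique(v)), integer(1))
  expect_gt(sum(n_classes == 1), 0)    # pure orders exist
  expect_gt(sum(n_classes > 1), 0)     # mixed orders exist
})

test_that("config invariants are validated", {
  expect_error(generator_config(p_leak = 1.2), class = "restrans_parameter_error")
  expect_error(generator_config(garden_timepoints_days = c(7, 1)),
               class = "restrans_parameter_error")
  expect_error(generator_config(n_populations = 0),
               class = "restrans_parameter_error")
  expect_error(generator_config(transient_pulses_per_asv = 99),
               class = "restrans_parameter_error")
  expect_error(generator_config(abundance_dispersion = 0),
               class = "restrans_parameter_error")
})

test_that("datasets round-trip through the on-disk TSV/YAML layout", {
  cfg <- small_config(seed = 11)
  d <- generate_dataset(cfg)
  out <- withr::local_tempdir()
  write_dataset(d, out)
  tab <- read_asv_table(file.path(out, "asv_table.tsv"))
  expect_identical(tab$counts, d$table$counts)
  meta <- read_metadata(file.path(out, "metadata.tsv"))
  expect_identical(meta$sample_id, d$metadata$sample_id)
  cfg_back <- read_generator_config(file.path(out, "generator_config.yaml"))
  expect_identical(unclass(cfg_back), unclass(cfg))
  d_back <- generate_dataset(cfg_back)
  expect_identical(d_back$table$counts, d$table$counts)
})
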