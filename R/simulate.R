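#' Configuration for the synthetic common-garden generator
#'
#' The generator emulates a multi-population common-garden transplant
#' design: several host populations are sampled in the field, then reared
#' in a shared environment and resampled repeatedly.  Defaults mirror the
#' study design the package targets: 6 populations, 5 field samples each,
#' and 4 garden samples per population at each of 8 timepoints (days 1, 2,
#' then weekly to day 42), i.e. 222 samples.
#'
#' Three ASV classes are planted.  *Residents* are restricted to a home
#' population (presence `p_present_resident` there, `p_leak` elsewhere,
#' field and garden alike).  *Core* ASVs are present everywhere with
#' probability `p_present_core`.  *Transients* model exchange with the
#' shared environmental pool: each transient ASV pulses through the common
#' water at `transient_pulses_per_asv` of the garden timepoints (drawn at
#' random per ASV; availability is shared across populations, since the
#' garden has one water supply).  During a pulse at day t it colonises a
#' sample of population P with probability `transient_hit_presence *
#' uptake_P(t)`, where `uptake_P(t) = uptake_floor + (1 - uptake_floor) *
#' (1 - exp(-lambda_P * t))` and the population-specific exchange rate
#' `lambda_P` is `exchange_rate_per_day` (a rate of exactly 0 means no
#' uptake at all).  Outside pulses a transient is absent from the garden;
#' field samples carry only the ambient baseline
#' `transient_base_presence`.  Because transient occurrences are
#' synchronised in time across populations while within-population pairs
#' mostly span different timepoints, transients co-occur across
#' populations more than within — the signature their flexibility score
#' detects.
#'
#' Present ASVs receive negative-binomial counts (size
#' `abundance_dispersion`) scaled so sample totals fluctuate log-normally
#' around `mean_depth`; a fraction `p_shallow` of samples is drawn shallow
#' (< 1000 reads) so the depth filter has work to do.
#'
#' @param n_populations Number of host populations (default 6).
#' @param n_field_per_pop Field samples per population (default 5).
#' @param garden_timepoints_days Strictly increasing garden sampling days.
#' @param n_garden_per_pop_per_timepoint Garden samples per population and
#'   timepoint (default 4).
#' @param n_tanks_per_pop Tanks per population; samples are assigned to
#'   tanks round-robin.  No tank effect is generated by default.
#' @param n_resident_asvs_per_pop,n_shared_core_asvs,n_transient_pool_asvs
#'   Class sizes (defaults 30 per population, 120, 200).
#' @param p_present_resident,p_leak,p_present_core,transient_base_presence
#'   Class presence probabilities (defaults 0.9, 0.02, 0.8, 0.05).
#' @param exchange_rate_per_day Per-population uptake rate lambda (per
#'   day); recycled to `n_populations`.  The default gives half the
#'   populations a slow (0.1) and half a fast (0.3) exchange rate.
#' @param transient_pulses_per_asv Number of garden timepoints at which
#'   each transient ASV is available (default 2).
#' @param transient_hit_presence,p_max_transient Within-pulse presence
#'   probability and a cap on the total transient presence probability.
#' @param uptake_floor Minimum fraction of the uptake curve available from
#'   day one (populations with a zero exchange rate take up nothing).
#' @param abundance_dispersion Negative-binomial size parameter.
#' @param mean_depth,depth_sdlog,p_shallow Sequencing-depth model.
#' @param seed Integer seed; regeneration with the same config is
#'   byte-identical.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_populations = 6L,
                             n_field_per_pop = 5L,
                             garden_timepoints_days = c(1, 2, 7, 14, 21, 28, 35, 42),
                             n_garden_per_pop_per_timepoint = 4L,
                             n_tanks_per_pop = 4L,
                             n_resident_asvs_per_pop = 30L,
                             n_shared_core_asvs = 120L,
                             n_transient_pool_asvs = 200L,
                             p_present_resident = 0.9,
                             p_leak = 0.02,
                             p_present_core = 0.8,
                             transient_base_presence = 0.05,
                             exchange_rate_per_day = c(0.1, 0.3),
                             transient_pulses_per_asv = 2L,
                             transient_hit_presence = 0.95,
                             p_max_transient = 0.95,
                             uptake_floor = 0.7,
                             abundance_dispersion = 0.5,
                             mean_depth = 20000,
                             depth_sdlog = 0.35,
                             p_shallow = 0.01,
                             seed = 1L) {
  cfg <- list(
    n_populations = as.integer(n_populations),
    n_field_per_pop = as.integer(n_field_per_pop),
    garden_timepoints_days = as.numeric(garden_timepoints_days),
    n_garden_per_pop_per_timepoint = as.integer(n_garden_per_pop_per_timepoint),
    n_tanks_per_pop = as.integer(n_tanks_per_pop),
    n_resident_asvs_per_pop = as.integer(n_resident_asvs_per_pop),
    n_shared_core_asvs = as.integer(n_shared_core_asvs),
    n_transient_pool_asvs = as.integer(n_transient_pool_asvs),
    p_present_resident = as.numeric(p_present_resident),
    p_leak = as.numeric(p_leak),
    p_present_core = as.numeric(p_present_core),
    transient_base_presence = as.numeric(transient_base_presence),
    exchange_rate_per_day = rep_len(as.numeric(exchange_rate_per_day),
                                    as.integer(n_populations)),
    transient_pulses_per_asv = as.integer(transient_pulses_per_asv),
    transient_hit_presence = as.numeric(transient_hit_presence),
    p_max_transient = as.numeric(p_max_transient),
    uptake_floor = as.numeric(uptake_floor),
    abundance_dispersion = as.numeric(abundance_dispersion),
    mean_depth = as.numeric(mean_depth),
    depth_sdlog = as.numeric(depth_sdlog),
    p_shallow = as.numeric(p_shallow),
    seed = as.integer(seed)
  )
  validate_generator_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

validate_generator_config <- function(cfg) {
  probs <- c(cfg$p_present_resident, cfg$p_leak, cfg$p_present_core,
             cfg$transient_base_presence,
             cfg$transient_hit_presence, cfg$p_max_transient,
             cfg$uptake_floor, cfg$p_shallow)
  if (any(probs < 0 | probs > 1)) stop_param("probabilities must lie in [0, 1]")
  counts <- c(cfg$n_populations, cfg$n_field_per_pop,
              cfg$n_garden_per_pop_per_timepoint, cfg$n_tanks_per_pop)
  if (any(counts < 1L)) stop_param("sample-layout counts must be positive")
  if (cfg$n_resident_asvs_per_pop < 0L || cfg$n_shared_core_asvs < 0L ||
      cfg$n_transient_pool_asvs < 0L) {
    stop_param("ASV class sizes must be non-negative")
  }
  tp <- cfg$garden_timepoints_days
  if (length(tp) > 1L && any(diff(tp) <= 0)) {
    stop_param("garden timepoints must be strictly increasing")
  }
  if (any(tp < 0)) stop_param("garden timepoints must be non-negative")
  if (any(cfg$exchange_rate_per_day < 0)) {
    stop_param("exchange rates must be non-negative")
  }
  if (cfg$transient_pulses_per_asv < 0L ||
      cfg$transient_pulses_per_asv > length(tp)) {
    stop_param("transient pulses per ASV must lie in 0..n_timepoints")
  }
  if (cfg$abundance_dispersion <= 0) stop_param("dispersion must be positive")
  if (cfg$mean_depth <= 0) stop_param("mean depth must be positive")
  invisible(cfg)
}

population_labels <- function(n) {
  base <- c("ME", "MA", "RI", "VA", "NC", "FL")
  if (n <= length(base)) base[seq_len(n)] else
    c(base, paste0("P", seq_len(n - length(base))))
}

build_sample_frame <- function(cfg) {
  pops <- population_labels(cfg$n_populations)
  field <- expand.grid(rep = seq_len(cfg$n_field_per_pop), population = pops,
                       stringsAsFactors = FALSE)
  field <- data.frame(
    sample_id = sprintf("%s_F%02d", field$population, field$rep),
    population = field$population,
    source = "field",
    timepoint = NA_real_,
    tank = NA_character_,
    stringsAsFactors = FALSE
  )
  garden <- expand.grid(rep = seq_len(cfg$n_garden_per_pop_per_timepoint),
                        timepoint = cfg$garden_timepoints_days,
                        population = pops, stringsAsFactors = FALSE)
  tp_str <- formatC(garden$timepoint, width = 2, flag = "0", format = "g")
  garden <- data.frame(
    sample_id = sprintf("%s_D%s_%d", garden$population, tp_str, garden$rep),
    population = garden$population,
    source = "common_garden",
    timepoint = garden$timepoint,
    tank = sprintf("%s_tank%d", garden$population,
                   ((garden$rep - 1L) %% cfg$n_tanks_per_pop) + 1L),
    stringsAsFactors = FALSE
  )
  rbind(field, garden)
}

build_truth <- function(cfg) {
  pops <- population_labels(cfg$n_populations)
  classes <- c(
    rep("resident", cfg$n_resident_asvs_per_pop * cfg$n_populations),
    rep("core", cfg$n_shared_core_asvs),
    rep("transient", cfg$n_transient_pool_asvs)
  )
  home <- c(
    rep(pops, each = cfg$n_resident_asvs_per_pop),
    rep(NA_character_, cfg$n_shared_core_asvs + cfg$n_transient_pool_asvs)
  )
  n_asv <- length(classes)
  if (n_asv == 0L) stop_param("config generates no ASVs")
  data.frame(
    asv_id = sprintf("ASV_%04d", seq_len(n_asv)),
    class = classes,
    home_population = home,
    stringsAsFactors = FALSE
  )
}

build_taxonomy <- function(truth) {
  n <- nrow(truth)
  order_lab <- character(n)
  counter <- c(resident = 0L, core = 0L, transient = 0L, null = 0L)
  for (i in seq_len(n)) {
    cls <- truth$class[i]
    counter[cls] <- counter[cls] + 1L
    k <- counter[cls]
    order_lab[i] <- if (k %% 10L == 0L) {
      "Mixedales"  # deliberately spans classes
    } else {
      switch(cls,
        resident = sprintf("Residentales_%d", (k %% 3L) + 1L),
        core = sprintf("Coreales_%d", (k %% 2L) + 1L),
        transient = sprintf("Transientales_%d", (k %% 2L) + 1L),
        null = "Nullales"
      )
    }
  }
  data.frame(
    asv_id = truth$asv_id,
    domain = "Bacteria",
    phylum = "Synthetophyta",
    class = "Synthetia",
    order = order_lab,
    family = ifelse(seq_len(n) %% 3L == 0L, "", "Synthetaceae"),
    genus = "",
    stringsAsFactors = FALSE
  )
}

# presence-probability matrix (samples x ASVs) given the pulse matrix
presence_probabilities <- function(cfg, samples, truth, pulses) {
  pops <- population_labels(cfg$n_populations)
  lambda <- stats::setNames(cfg$exchange_rate_per_day, pops)
  n_s <- nrow(samples)
  n_a <- nrow(truth)
  prob <- matrix(0, n_s, n_a)
  is_garden <- samples$source == "common_garden"

  for (j in seq_len(n_a)) {
    cls <- truth$class[j]
    if (cls == "resident") {
      prob[, j] <- ifelse(samples$population == truth$home_population[j],
                          cfg$p_present_resident, cfg$p_leak)
    } else if (cls == "core") {
      prob[, j] <- cfg$p_present_core
    } else {  # transient: field at ambient base level, garden pulse-driven
      p <- rep(cfg$transient_base_presence, n_s)
      if (any(is_garden)) {
        t_days <- samples$timepoint[is_garden]
        tp_idx <- match(t_days, cfg$garden_timepoints_days)
        avail <- pulses[tp_idx, j]
        lam_g <- lambda[samples$population[is_garden]]
        uptake <- cfg$uptake_floor +
          (1 - cfg$uptake_floor) * (1 - exp(-lam_g * t_days))
        uptake[lam_g == 0] <- 0
        p[is_garden] <- pmin(cfg$p_max_transient,
                             avail * cfg$transient_hit_presence * uptake)
      }
      prob[, j] <- p
    }
  }
  prob
}

draw_counts <- function(cfg, prob, samples, truth) {
  n_s <- nrow(prob)
  n_a <- ncol(prob)
  present <- matrix(stats::rbinom(n_s * n_a, 1L, as.vector(prob)), n_s, n_a)
  depth <- round(stats::rlnorm(n_s,
                               log(cfg$mean_depth) - cfg$depth_sdlog^2 / 2,
                               cfg$depth_sdlog))
  shallow <- stats::runif(n_s) < cfg$p_shallow
  depth[shallow] <- sample(100:999, sum(shallow), replace = TRUE)
  counts <- matrix(0L, n_s, n_a)
  for (i in seq_len(n_s)) {
    idx <- which(present[i, ] == 1L)
    if (length(idx) == 0L) next
    mu <- max(depth[i] / length(idx) - 1, 0.1)
    counts[i, idx] <- 1L + stats::rnbinom(length(idx),
                                          size = cfg$abundance_dispersion,
                                          mu = mu)
  }
  dimnames(counts) <- list(samples$sample_id, truth$asv_id)
  counts
}

#' Generate a synthetic common-garden dataset with known ground truth
#'
#' @param config A [generator_config()].
#' @return A list with elements `table` (an [asv_table]), `metadata`,
#'   `taxonomy`, `truth` (per-ASV class and home population), and `config`
#'   (the resolved configuration).
#' @export
generate_dataset <- function(config) {
  validate_generator_config(config)
  samples <- build_sample_frame(config)
  truth <- build_truth(config)
  taxonomy <- build_taxonomy(truth)
  out <- with_rng_seed(config$seed, {
    n_tp <- length(config$garden_timepoints_days)
    pulses <- matrix(0L, n_tp, nrow(truth))
    for (j in which(truth$class == "transient")) {
      pulses[sample.int(n_tp, config$transient_pulses_per_asv), j] <- 1L
    }
    prob <- presence_probabilities(config, samples, truth, pulses)
    draw_counts(config, prob, samples, truth)
  })
  list(
    table = asv_table(out),
    metadata = validate_metadata(samples),
    taxonomy = taxonomy,
    truth = truth,
    config = config
  )
}

#' Generate a structure-free null dataset
#'
#' Keeps the sample layout (populations, sources, timepoints) but removes
#' all population and temporal structure: every ASV has a single presence
#' probability, drawn once per ASV and shared by all samples.  Population
#' labels are labels only; tests run on this output calibrate type-I error.
#'
#' @param config A [generator_config()].
#' @return As [generate_dataset()]; `truth$class` is `"null"` throughout.
#' @export
generate_null_dataset <- function(config) {
  validate_generator_config(config)
  samples <- build_sample_frame(config)
  truth <- build_truth(config)
  truth$class <- "null"
  truth$home_population <- NA_character_
  taxonomy <- build_taxonomy(truth)
  out <- with_rng_seed(config$seed, {
    p_asv <- stats::runif(nrow(truth), min = 0.05, max = 0.6)
    prob <- matrix(p_asv, nrow(samples), nrow(truth), byrow = TRUE)
    draw_counts(config, prob, samples, truth)
  })
  list(
    table = asv_table(out),
    metadata = validate_metadata(samples),
    taxonomy = taxonomy,
    truth = truth,
    config = config
  )
}

#' Write the generator outputs as TSV files
#'
#' Writes `asv_table.tsv`, `metadata.tsv`, `taxonomy.tsv`, `truth.tsv` and
#' the resolved configuration `generator_config.yaml` into `out_dir`.
#'
#' @param dataset A [generate_dataset()] result.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_asv_table(dataset$table, file.path(out_dir, "asv_table.tsv"))
  write_metadata(dataset$metadata, file.path(out_dir, "metadata.tsv"))
  utils::write.table(dataset$taxonomy, file.path(out_dir, "taxonomy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$truth, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(dataset$config),
                   file.path(out_dir, "generator_config.yaml"))
  invisible(out_dir)
}

#' Read a generator configuration from a YAML file
#'
#' The file is a flat key-value document whose keys mirror the
#' [generator_config()] arguments; missing keys fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @return A [generator_config()].
#' @export
read_generator_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(generator_config)))
  if (length(unknown) > 0L) {
    stop_param(paste0("unknown generator config key(s): ",
                      paste(unknown, collapse = ", ")))
  }
  do.call(generator_config, vals)
}
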