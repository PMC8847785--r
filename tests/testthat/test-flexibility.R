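# Exhaustive-pair oracle for the per-ASV sharing components.
sharing_oracle <- function(presence, pop) {
  pairs <- utils::combn(length(presence), 2)
  w_scores <- c(); b_scores <- c()
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    if (!presence[i] && !presence[j]) next   # double absence excluded
    score <- as.numeric(presence[i] && presence[j])
    if (pop[i] == pop[j]) w_scores <- c(w_scores, score)
    else b_scores <- c(b_scores, score)
  }
  list(s_within = if (length(w_scores)) mean(w_scores) else NA_real_,
       s_between = if (length(b_scores)) mean(b_scores) else NA_real_,
       n_within = length(w_scores), n_between = length(b_scores))
}

two_pop_meta <- function() {
  toy_meta(c("A1", "A2", "B1", "B2"), c("A", "A", "B", "B"))
}

test_that("per-ASV sharing matches exhaustive pair enumeration on worked cases", {
  meta <- two_pop_meta()
  # ASV in both A samples, absent from B: s_w = 1 (1 eligible A pair,
  # B pair excluded), s_b = 0 (4 mixed pairs)
  tab <- toy_table(cbind(A1 = c(1L, 1L, 0L, 0L), pad = c(1L, 1L, 1L, 1L)),
                   samples = meta$sample_id)
  sh <- per_asv_sharing(tab, meta, "A1")
  expect_equal(sh$s_within, 1)
  expect_equal(sh$s_between, 0)
  expect_identical(sh$n_within_pairs, 1L)
  expect_identical(sh$n_between_pairs, 4L)

  # ASV in exactly one sample of each population: s_w = 0, s_b = 1/3
  tab2 <- toy_table(cbind(A1 = c(1L, 0L, 1L, 0L), pad = rep(1L, 4)),
                    samples = meta$sample_id)
  sh2 <- per_asv_sharing(tab2, meta, "A1")
  expect_equal(sh2$s_within, 0)
  expect_equal(sh2$s_between, 1 / 3)
  expect_identical(sh2$n_between_pairs, 3L)

  # ubiquitous ASV: both components 1
  sh3 <- per_asv_sharing(tab2, meta, "pad")
  expect_equal(sh3$s_within, 1)
  expect_equal(sh3$s_between, 1)
})

test_that("vectorised sharing agrees with the pair-enumeration oracle", {
  set.seed(17)
  for (rep in 1:5) {
    n <- 12
    meta <- toy_meta(paste0("S", 1:n), sample(c("A", "B", "C"), n, TRUE))
    tab <- random_table(n, 15, p = 0.5)
    for (asv in sample(asv_ids(tab), 5)) {
      sh <- per_asv_sharing(tab, meta, asv)
      orc <- sharing_oracle(presence_matrix(tab)[, asv], meta$population)
      expect_equal(sh$s_within, orc$s_within)
      expect_equal(sh$s_between, orc$s_between)
      expect_identical(sh$n_within_pairs, orc$n_within)
      expect_identical(sh$n_between_pairs, orc$n_between)
    }
  }
})

test_that("flexibility scores classify the worked cases as documented", {
  meta <- two_pop_meta()
  tab <- toy_table(cbind(restricted = c(1L, 1L, 0L, 0L),
                         crosser = c(1L, 0L, 1L, 0L),
                         everywhere = rep(1L, 4)),
                   samples = meta$sample_id)
  fs <- flexibility_scores(tab, meta, min_prevalence = 0)
  expect_identical(fs$fs[fs$asv_id == "restricted"], Inf)
  expect_identical(fs$residency[fs$asv_id == "restricted"], "resident")
  expect_equal(fs$fs[fs$asv_id == "crosser"], 0)
  expect_identical(fs$residency[fs$asv_id == "crosser"], "transient")
  expect_equal(fs$fs[fs$asv_id == "everywhere"], 1)
  expect_identical(fs$residency[fs$asv_id == "everywhere"], "neutral")
  expect_equal(fs$prevalence[fs$asv_id == "crosser"], 0.5)
})

test_that("sharing is invariant to sample order and abundance scaling", {
  set.seed(18)
  n <- 10
  meta <- toy_meta(paste0("S", 1:n), rep(c("A", "B"), each = 5))
  tab <- random_table(n, 12, p = 0.5)
  fs <- flexibility_scores(tab, meta, min_prevalence = 0)

  perm <- sample(n)
  tab_perm <- asv_table(tab$counts[perm, ])
  fs_perm <- flexibility_scores(tab_perm, meta[perm, ], min_prevalence = 0)
  expect_equal(fs_perm[order(fs_perm$asv_id), ],
               fs[order(fs$asv_id), ], ignore_attr = TRUE)

  scaled <- asv_table(tab$counts * 7L)
  fs_scaled <- flexibility_scores(scaled, meta, min_prevalence = 0)
  expect_equal(fs_scaled$fs, fs$fs)
})

test_that("smoothing and the dissimilarity mode behave as documented", {
  meta <- two_pop_meta()
  tab <- toy_table(cbind(restricted = c(1L, 1L, 0L, 0L),
                         everywhere = rep(1L, 4)),
                   samples = meta$sample_id)
  sm <- flexibility_scores(tab, meta, min_prevalence = 0, smoothing = 0.5)
  expect_equal(sm$fs[sm$asv_id == "restricted"], 1.5 / 0.5)  # finite now

  dm <- flexibility_scores(tab, meta, min_prevalence = 0,
                           fs_mode = "dissimilarity")
  # restricted: (1 - 1)/(1 - 0) = 0 -> still called resident in this mode
  expect_equal(dm$fs[dm$asv_id == "restricted"], 0)
  expect_identical(dm$residency[dm$asv_id == "restricted"], "resident")
})

test_that("prevalence filtering and design errors are enforced", {
  meta <- two_pop_meta()
  tab <- toy_table(cbind(rare = c(1L, 0L, 0L, 0L), common = rep(1L, 4)),
                   samples = meta$sample_id)
  fs <- flexibility_scores(tab, meta, min_prevalence = 0.5)
  expect_identical(fs$asv_id, "common")

  meta1 <- toy_meta(meta$sample_id, rep("A", 4))
  expect_error(flexibility_scores(tab, meta1, min_prevalence = 0),
               class = "restrans_design_error")
})

test_that("tail sizes follow the ceiling rule, including the n = 1375 case", {
  make_fs <- function(n) {
    structure(data.frame(asv_id = sprintf("ASV_%05d", seq_len(n)),
                         fs = seq_len(n) + 0,
                         prevalence = rep(0.5, n)),
              class = c("flexibility_table", "data.frame"))
  }
  for (case in list(c(1375, 0.01, 14), c(100, 0.01, 1), c(200, 0.05, 10),
                    c(57, 0.02, 2), c(999, 0.013, 13))) {
    sel <- select_tails(make_fs(case[1]), case[2])
    expect_identical(length(sel$top_asvs), as.integer(case[3]))
    expect_identical(length(sel$bottom_asvs), as.integer(case[3]))
  }
  sel <- select_tails(make_fs(1375), 0.01)
  expect_identical(length(union(sel$top_asvs, sel$bottom_asvs)), 28L)
})

test_that("tail ranking puts +Inf on top and breaks ties by prevalence then ID", {
  fs <- structure(data.frame(
    asv_id = c("a_inf", "b_hi", "c_tie", "a_tie", "d_lo", "e_na"),
    fs = c(Inf, 5, 2, 2, 0.1, NA),
    prevalence = c(0.2, 0.9, 0.8, 0.3, 0.5, 0.5)),
    class = c("flexibility_table", "data.frame"))
  sel <- select_tails(fs, 0.45)  # 3 per tail out of 5 ranked
  expect_identical(sel$top_asvs, c("a_inf", "b_hi", "c_tie"))
  expect_identical(sel$bottom_asvs, c("d_lo", "c_tie", "a_tie"))
  expect_error(select_tails(fs, 0.5), class = "restrans_parameter_error")
  expect_error(select_tails(fs, 0), class = "restrans_parameter_error")
})

test_that("order-level summaries reproduce pure, single and mixed patterns", {
  fs <- structure(data.frame(
    asv_id = paste0("A", 1:6),
    fs = c(2, 3, 0.5, 0.2, 1.5, NA),
    prevalence = rep(0.5, 6)),
    class = c("flexibility_table", "data.frame"))
  tax <- data.frame(asv_id = paste0("A", 1:5),
                    order = c("Pure", "Pure", "Low", "Mixed", "Mixed"),
                    stringsAsFactors = FALSE)
  sm <- order_level_summary(fs, tax)
  expect_equal(sm$fraction_fs_gt1[sm$order == "Pure"], 1)
  expect_equal(sm$fraction_fs_gt1[sm$order == "Low"], 0)
  low <- sm[sm$order == "Low", ]
  expect_true(all(low[c("min", "q1", "median", "q3", "max")] == 0.5))
  mixed <- sm[sm$order == "Mixed", ]
  expect_true(mixed$min < 1 && mixed$max > 1)
  # A6 has fs = NA (not scored); A1..A5 all covered, so no 'unclassified'
  expect_false("unclassified" %in% sm$order)

  tax_none <- data.frame(asv_id = "Z9", order = "X")
  expect_error(order_level_summary(fs, tax_none),
               class = "restrans_empty_result_error")
})

test_that("flexibility table round-trips through TSV", {
  meta <- two_pop_meta()
  tab <- toy_table(cbind(a = c(1L, 1L, 0L, 0L), b = rep(1L, 4)),
                   samples = meta$sample_id)
  fs <- flexibility_scores(tab, meta, min_prevalence = 0)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_flexibility_table(fs, f)
  back <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(back), nrow(fs))
  expect_equal(back$s_within, fs$s_within)
})
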