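test_that("pseudo-F and R-squared match the hand-evaluated worked matrix", {
  # within-pair d = 0.1, between-pair d = 1:
  # SS_total = (2*0.01 + 4*1)/4 = 1.005, SS_within = 2*(0.01/2) = 0.01,
  # pseudo-F = (0.995/1)/(0.01/2) = 199
  d <- worked_matrix_4()
  res <- permanova(d, c("g1", "g1", "g2", "g2"), exhaustive = TRUE)
  expect_equal(res$pseudo_F, 199)
  expect_equal(res$ss_total, 1.005)
  expect_equal(res$ss_within, 0.01)
  expect_equal(res$R_squared, 0.995 / 1.005)
  expect_identical(res$df_among, 1L)
  expect_identical(res$df_within, 2L)
})

test_that("exhaustive enumeration reproduces the exact permutation p-value", {
  d <- worked_matrix_4()
  res <- permanova(d, c("g1", "g1", "g2", "g2"), exhaustive = TRUE)
  # 3 distinct 2+2 partitions; only the true one reaches F = 199
  expect_equal(res$p_value, 1 / 3)

  # sampled p agrees within Monte-Carlo error (3 SE)
  res_mc <- permanova(d, c("g1", "g1", "g2", "g2"),
                      n_permutations = 999, seed = 1)
  se <- sqrt(res$p_value * (1 - res$p_value) / 999)
  expect_lt(abs(res_mc$p_value - res$p_value), 3 * se + 1e-3)
})

test_that("equal distances give permutation-invariant F and p = 1", {
  d <- matrix(0.7, 5, 5, dimnames = list(paste0("S", 1:5), paste0("S", 1:5)))
  diag(d) <- 0
  res <- permanova(d, c("a", "a", "b", "b", "b"), n_permutations = 99,
                   seed = 2)
  expect_equal(res$p_value, 1)
})

test_that("statistics are invariant to sample relabeling and to the seed", {
  set.seed(21)
  tab <- random_table(12, 30)
  d <- sorensen_dice_matrix(tab)
  grp <- rep(c("x", "y", "z"), each = 4)
  names(grp) <- rownames(d)
  r1 <- permanova(d, grp, n_permutations = 199, seed = 5)
  perm <- sample(rownames(d))
  r2 <- permanova(d[perm, perm], grp[perm], n_permutations = 199, seed = 99)
  expect_equal(r1$pseudo_F, r2$pseudo_F)
  expect_equal(r1$R_squared, r2$R_squared)
  r3 <- permanova(d, grp, n_permutations = 199, seed = 12345)
  expect_equal(r1$pseudo_F, r3$pseudo_F)
})

test_that("permanova agrees with vegan::adonis2 on random data", {
  set.seed(31)
  tab <- random_table(15, 40)
  d <- sorensen_dice_matrix(tab)
  grp <- sample(rep(c("a", "b", "c"), each = 5))
  mine <- permanova(d, grp, n_permutations = 99, seed = 1)
  df <- data.frame(grp = grp)
  veg <- vegan::adonis2(stats::as.dist(d) ~ grp, data = df, permutations = 99)
  expect_equal(mine$pseudo_F, veg$F[1], tolerance = 1e-10)
  expect_equal(mine$R_squared, veg$R2[1], tolerance = 1e-10)
})

test_that("degenerate designs raise design errors", {
  d <- worked_matrix_4()
  expect_error(permanova(d, rep("g", 4), seed = 1),
               class = "restrans_design_error")
  expect_error(permanova(d, paste0("g", 1:4), seed = 1),
               class = "restrans_design_error")
  expect_error(permanova(d, c("a", "a", "b", "b")),
               class = "restrans_parameter_error")  # missing seed
})

test_that("dispersion distances match coordinate geometry on a planted 2-D set", {
  # two groups of 4 points in the plane; Euclidean distances embed exactly,
  # so distance-to-centroid must match direct computation
  set.seed(41)
  pts <- rbind(matrix(rnorm(8), 4, 2), matrix(rnorm(8, mean = 3), 4, 2))
  rownames(pts) <- paste0("S", 1:8)
  d <- as.matrix(stats::dist(pts))
  grp <- rep(c("a", "b"), each = 4)
  res <- dispersion_test(d, grp, n_permutations = 99, seed = 1)
  expected <- unlist(lapply(split(seq_len(8), grp), function(idx) {
    ctr <- colMeans(pts[idx, , drop = FALSE])
    sqrt(rowSums(sweep(pts[idx, , drop = FALSE], 2, ctr)^2))
  }), use.names = FALSE)
  expect_equal(unname(res$distances), expected, tolerance = 1e-10)
})

test_that("congruent group geometries give F near zero", {
  # two groups with identical internal shape (translated copies)
  pts <- rbind(c(0, 0), c(1, 0), c(0, 1),
               c(10, 10), c(11, 10), c(10, 11))
  rownames(pts) <- paste0("S", 1:6)
  d <- as.matrix(stats::dist(pts))
  res <- dispersion_test(d, rep(c("a", "b"), each = 3),
                         n_permutations = 99, seed = 1)
  expect_lt(res$F_statistic, 1e-10)
  expect_gt(res$p_value, 0.5)
})

test_that("dispersion_test agrees with vegan::betadisper (centroid type)", {
  set.seed(51)
  tab <- random_table(14, 30)
  d <- sorensen_dice_matrix(tab)
  grp <- rep(c("a", "b"), each = 7)
  mine <- dispersion_test(d, grp, n_permutations = 99, seed = 1)
  veg <- vegan::betadisper(stats::as.dist(d), grp, type = "centroid")
  expect_equal(unname(mine$distances), unname(veg$distances),
               tolerance = 1e-8)
  expect_equal(unname(stats::anova(veg)$`F value`[1]), mine$F_statistic,
               tolerance = 1e-8)
})

test_that("a group of size one is rejected by name", {
  d <- worked_matrix_4()
  expect_error(dispersion_test(d, c("a", "a", "a", "solo"),
                               n_permutations = 9, seed = 1),
               "solo")
})
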