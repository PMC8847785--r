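# Distance-based group tests written directly from the sum-of-squares
# definitions, so that every statistic the pipeline reports is reproducible
# from the formulas documented here.

ss_partition <- function(d2, groups) {
  n <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1L) {
      sub <- d2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  c(total = ss_total, within = ss_within, among = ss_total - ss_within)
}

pseudo_f_from_ss <- function(ss, n, g) {
  if (ss[["within"]] <= 0) return(Inf)
  (ss[["among"]] / (g - 1)) / (ss[["within"]] / (n - g))
}

# SS_within for many label permutations at once.  perm is an n x n_perm
# integer matrix of permuted sample indices; returns a vector of pseudo-F.
permuted_pseudo_f <- function(d2, groups, perm) {
  n <- nrow(d2)
  lev <- unique(groups)
  g <- length(lev)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  n_per <- as.vector(table(factor(groups, levels = lev)))
  f <- numeric(ncol(perm))
  for (k in seq_len(ncol(perm))) {
    pg <- groups[perm[, k]]
    e <- outer(pg, lev, "==") * 1        # n x g indicator
    gram <- crossprod(e, d2) %*% e       # sum over ordered pairs per group
    ss_w <- sum(diag(gram) / (2 * n_per))
    f[k] <- if (ss_w <= 0) Inf else
      ((ss_total - ss_w) / (g - 1)) / (ss_w / (n - g))
  }
  f
}

check_groups <- function(dist, groups) {
  n <- nrow(dist)
  if (is.null(names(groups))) {
    if (length(groups) != n) stop_param("'groups' must cover every sample")
  } else {
    missing_ids <- setdiff(rownames(dist), names(groups))
    if (length(missing_ids) > 0L) {
      stop_param(paste0("'groups' missing sample(s): ",
                        paste(missing_ids, collapse = ", ")))
    }
    groups <- groups[rownames(dist)]
  }
  groups <- as.character(groups)
  if (length(unique(groups)) < 2L) {
    stop_design("at least two groups are required")
  }
  if (length(unique(groups)) >= n) {
    stop_design("degenerate design: every sample is its own group")
  }
  groups
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Partitions the total sum of squared dissimilarities among and within
#' groups and tests the group effect by permuting sample labels.  With N
#' samples in g groups,
#' \deqn{SS_{total} = \frac{1}{N}\sum_{i<j} d_{ij}^2, \quad
#'       SS_{within} = \sum_{g}\frac{1}{n_g}\sum_{i<j \in g} d_{ij}^2,}
#' \eqn{SS_{among} = SS_{total} - SS_{within}}, and the pseudo-F statistic is
#' \eqn{(SS_{among}/(g-1)) / (SS_{within}/(N-g))}.  The permutation p-value
#' uses the add-one convention \eqn{p = (1 + \#\{F^\pi \ge F\}) / (1 + n_{perm})}
#' so it is never exactly zero and has resolution 1/(n_permutations + 1).
#'
#' @param dist Symmetric distance matrix with sample IDs as dimnames.
#' @param groups Per-sample group labels, either unnamed in row order of
#'   `dist` or named by sample ID.
#' @param n_permutations Number of label permutations (default 999).
#' @param seed Integer seed for the permutations (required; no hidden RNG
#'   state).
#' @param exhaustive If `TRUE`, enumerate all distinct label arrangements
#'   instead of sampling; the p-value is then the exact fraction of
#'   arrangements (including the observed one) with \eqn{F^\pi \ge F}.
#'   Only sensible for small designs.
#' @return A list of class `permanova_result` with elements `pseudo_F`,
#'   `R_squared`, `p_value`, `n_permutations`, `df_among`, `df_within`,
#'   `ss_among`, `ss_within`, `ss_total`.
#' @export
permanova <- function(dist, groups, n_permutations = 999L, seed = NULL,
                      exhaustive = FALSE) {
  groups <- check_groups(dist, groups)
  n <- nrow(dist)
  g <- length(unique(groups))
  d2 <- dist^2
  ss <- ss_partition(d2, groups)
  f_obs <- pseudo_f_from_ss(ss, n, g)

  if (exhaustive) {
    perms <- all_label_permutations(groups)
    f_perm <- permuted_pseudo_f(d2, groups, perms)
    p <- mean(f_perm >= f_obs - 1e-12)
    n_perm_used <- ncol(perms)
  } else {
    if (is.null(seed)) stop_param("'seed' is required for sampled permutations")
    if (n_permutations < 1L) stop_param("'n_permutations' must be positive")
    perms <- with_rng_seed(seed, {
      vapply(seq_len(n_permutations), function(i) sample.int(n), integer(n))
    })
    f_perm <- permuted_pseudo_f(d2, groups, perms)
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_permutations)
    n_perm_used <- n_permutations
  }

  structure(list(
    pseudo_F = f_obs,
    R_squared = if (ss[["total"]] > 0) ss[["among"]] / ss[["total"]] else NA_real_,
    p_value = p,
    n_permutations = n_perm_used,
    df_among = g - 1L,
    df_within = n - g,
    ss_among = unname(ss[["among"]]),
    ss_within = unname(ss[["within"]]),
    ss_total = unname(ss[["total"]])
  ), class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: pseudo-F = %.4g (df %d, %d), R2 = %.4f, p = %.4g (%d permutations)\n",
    x$pseudo_F, x$df_among, x$df_within, x$R_squared, x$p_value,
    x$n_permutations
  ))
  invisible(x)
}

# All distinct arrangements of a label multiset, as an index-permutation
# matrix (n x n_arrangements) into the original group vector.
all_label_permutations <- function(groups) {
  n <- length(groups)
  # enumerate distinct permutations of the label vector via recursion on
  # label counts, recording for each arrangement an index vector that maps
  # positions to original positions carrying the right label
  lev <- unique(groups)
  pools <- lapply(lev, function(l) which(groups == l))
  counts0 <- vapply(pools, length, integer(1))
  res <- list()
  rec <- function(pos, counts, taken) {
    if (pos > n) {
      res[[length(res) + 1L]] <<- taken
      return(invisible(NULL))
    }
    for (li in seq_along(lev)) {
      if (counts[li] > 0L) {
        counts[li] <- counts[li] - 1L
        idx <- pools[[li]][counts0[li] - counts[li]]
        rec(pos + 1L, counts, c(taken, idx))
        counts[li] <- counts[li] + 1L
      }
    }
  }
  rec(1L, counts0, integer(0))
  matrix(unlist(res), nrow = n)
}

#' Homogeneity of multivariate group dispersions
#'
#' Embeds the samples by principal-coordinates decomposition of the doubly
#' centered \eqn{-\frac{1}{2} d^2} matrix, keeping axes with negative
#' eigenvalues separately.  Each sample's dispersion is its distance to its
#' group centroid, computed as the square root of (squared real-axis
#' distance minus squared imaginary-axis distance), floored at zero.  The
#' statistic is the one-way ANOVA F over these distances; the p-value
#' permutes the group labels of the distances (centroids are not refitted
#' under permutation).
#'
#' @inheritParams permanova
#' @return A list of class `dispersion_result` with `group_dispersions`,
#'   `F_statistic`, `p_value`, `n_permutations`, and `distances` (per-sample
#'   distance to group centroid, named by sample).
#' @export
dispersion_test <- function(dist, groups, n_permutations = 999L, seed = NULL) {
  groups <- check_groups(dist, groups)
  tab <- table(groups)
  if (any(tab < 2L)) {
    stop_design(paste0("dispersion undefined for group(s) of size 1: ",
                       paste(names(tab)[tab < 2L], collapse = ", ")))
  }
  if (is.null(seed)) stop_param("'seed' is required for the permutation test")
  n <- nrow(dist)
  a <- -0.5 * dist^2
  g_mat <- a - matrix(rowMeans(a), n, n) -
    matrix(colMeans(a), n, n, byrow = TRUE) + mean(a)
  eig <- eigen(g_mat, symmetric = TRUE)
  keep <- abs(eig$values) > max(abs(eig$values)) * 1e-10
  lambda <- eig$values[keep]
  vec <- eig$vectors[, keep, drop = FALSE]
  coords <- sweep(vec, 2L, sqrt(abs(lambda)), "*")
  is_real <- lambda > 0

  dist_to_centroid <- numeric(n)
  for (g in unique(groups)) {
    idx <- which(groups == g)
    centroid <- colMeans(coords[idx, , drop = FALSE])
    delta2 <- sweep(coords[idx, , drop = FALSE], 2L, centroid)^2
    z2 <- rowSums(delta2[, is_real, drop = FALSE]) -
      rowSums(delta2[, !is_real, drop = FALSE])
    dist_to_centroid[idx] <- sqrt(pmax(z2, 0))
  }
  names(dist_to_centroid) <- rownames(dist)

  f_obs <- anova_f(dist_to_centroid, groups)
  f_perm <- with_rng_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      anova_f(dist_to_centroid, groups[sample.int(n)])
    }, numeric(1))
  })
  p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_permutations)

  structure(list(
    group_dispersions = tapply(dist_to_centroid, groups, mean),
    F_statistic = f_obs,
    p_value = p,
    n_permutations = n_permutations,
    distances = dist_to_centroid
  ), class = "dispersion_result")
}

anova_f <- function(y, groups) {
  n <- length(y)
  lev <- unique(groups)
  g <- length(lev)
  grand <- mean(y)
  ss_b <- 0
  ss_w <- 0
  for (l in lev) {
    yi <- y[groups == l]
    ss_b <- ss_b + length(yi) * (mean(yi) - grand)^2
    ss_w <- ss_w + sum((yi - mean(yi))^2)
  }
  if (ss_w <= 0) return(if (ss_b <= 0) 0 else Inf)
  (ss_b / (g - 1)) / (ss_w / (n - g))
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat(sprintf("Dispersion homogeneity: F = %.4g, p = %.4g (%d permutations)\n",
              x$F_statistic, x$p_value, x$n_permutations))
  invisible(x)
}
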