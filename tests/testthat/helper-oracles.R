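# Independent oracles used across the suite.  These deliberately avoid the
# package's own algorithms: hulls are evaluated by exhaustive chord
# enumeration, pair statistics by explicit set operations.

# ---- brute-force dip oracle ---------------------------------------------
# Greatest-convex-minorant value at xt via exhaustive chords.
chord_lower <- function(X, Y, xt) {
  v <- Inf
  for (i in seq_along(X)) if (X[i] == xt) v <- min(v, Y[i])
  for (i in seq_along(X)) for (j in seq_along(X)) {
    if (X[i] < xt && X[j] > xt) {
      v <- min(v, Y[i] + (Y[j] - Y[i]) * (xt - X[i]) / (X[j] - X[i]))
    }
  }
  v
}
chord_upper <- function(X, Y, xt) {
  v <- -Inf
  for (i in seq_along(X)) if (X[i] == xt) v <- max(v, Y[i])
  for (i in seq_along(X)) for (j in seq_along(X)) {
    if (X[i] < xt && X[j] > xt) {
      v <- max(v, Y[i] + (Y[j] - Y[i]) * (xt - X[i]) / (X[j] - X[i]))
    }
  }
  v
}

# Smallest sup-norm distance from the ECDF of x to a unimodal CDF, by
# scanning every candidate mode: each data value (atom allowed) and each
# between-value gap, whose left/right requirements cross monotonically and
# are located by bisection.
dip_oracle <- function(x) {
  x <- sort(x)
  n <- length(x)
  u <- unique(x)
  m <- length(u)
  b <- vapply(u, function(v) sum(x < v), numeric(1))
  cc <- vapply(u, function(v) sum(x <= v), numeric(1))
  if (m == 1) return(0)
  Lgap <- function(j, pos) {
    max(0, vapply(seq_len(j), function(k)
      cc[k] - chord_lower(c(u[1:j], pos), c(b[1:j], cc[j]), u[k]),
      numeric(1)))
  }
  Rgap <- function(j, pos) {
    max(0, vapply((j + 1):m, function(k)
      chord_upper(c(pos, u[(j + 1):m]), c(cc[j], cc[(j + 1):m]), u[k]) - b[k],
      numeric(1)))
  }
  best <- Inf
  for (j in seq_len(m)) {
    L <- if (j > 1) max(0, vapply(seq_len(j - 1), function(k)
      cc[k] - chord_lower(u[1:j], b[1:j], u[k]), numeric(1))) else 0
    R <- if (j < m) max(0, vapply((j + 1):m, function(k)
      chord_upper(u[j:m], cc[j:m], u[k]) - b[k], numeric(1))) else 0
    best <- min(best, max(L, R))
  }
  for (j in seq_len(m - 1)) {
    eps <- (u[j + 1] - u[j]) * 1e-12
    lo <- u[j] + eps
    hi <- u[j + 1] - eps
    f <- function(p) max(Lgap(j, p), Rgap(j, p))
    g <- function(p) Lgap(j, p) - Rgap(j, p)
    best <- min(best, f(lo), f(hi))
    if (g(lo) < 0 && g(hi) > 0) {
      for (it in 1:80) {
        mid <- (lo + hi) / 2
        if (g(mid) < 0) lo <- mid else hi <- mid
      }
      best <- min(best, f(lo), f(hi))
    }
  }
  best / (2 * n)
}

# ---- set-based Sorensen-Dice oracle -------------------------------------
sorensen_oracle <- function(counts) {
  n <- nrow(counts)
  d <- matrix(0, n, n, dimnames = list(rownames(counts), rownames(counts)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    si <- which(counts[i, ] > 0)
    sj <- which(counts[j, ] > 0)
    a <- length(intersect(si, sj))
    b <- length(setdiff(si, sj))
    cc <- length(setdiff(sj, si))
    d[i, j] <- 1 - 2 * a / (2 * a + b + cc)
  }
  d
}

# ---- tiny fixtures -------------------------------------------------------
toy_table <- function(counts, samples = NULL, asvs = NULL) {
  counts <- as.matrix(counts)
  if (is.null(samples)) {
    samples <- rownames(counts)
    if (is.null(samples)) samples <- paste0("S", seq_len(nrow(counts)))
  }
  if (is.null(asvs)) {
    asvs <- colnames(counts)
    if (is.null(asvs)) asvs <- paste0("A", seq_len(ncol(counts)))
  }
  dimnames(counts) <- list(samples, asvs)
  asv_table(counts)
}

toy_meta <- function(sample_id, population, source = "field",
                     timepoint = NA_real_, tank = NA_character_) {
  data.frame(sample_id = sample_id, population = population,
             source = source, timepoint = timepoint, tank = tank,
             stringsAsFactors = FALSE)
}

random_table <- function(n_samples, n_asvs, p = 0.4, max_count = 20) {
  m <- matrix(rbinom(n_samples * n_asvs, 1, p) *
                sample.int(max_count, n_samples * n_asvs, replace = TRUE),
              n_samples, n_asvs)
  # ensure no all-zero sample
  for (i in seq_len(n_samples)) {
    if (all(m[i, ] == 0)) m[i, sample.int(n_asvs, 1)] <- 1L
  }
  toy_table(m)
}

subset_samples_for_test <- function(tab, ids) {
  asv_table(tab$counts[ids, , drop = FALSE])
}

# 4-sample worked distance matrix: two groups of two, within-pair distance
# 0.1, between-pair distance 1
worked_matrix_4 <- function() {
  d <- matrix(1, 4, 4, dimnames = list(paste0("S", 1:4), paste0("S", 1:4)))
  diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 0.1
  d[3, 4] <- d[4, 3] <- 0.1
  d
}
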