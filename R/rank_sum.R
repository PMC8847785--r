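#' Two-sample Wilcoxon / Mann-Whitney rank-sum test
#'
#' Computes the Mann-Whitney U statistic from midranks.  When
#' `n_a * n_b <= 400` and there are no ties the p-value is exact, from the
#' full null distribution of U; otherwise a normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param values_a,values_b Numeric vectors (both non-empty).
#' @param alternative One of `"two_sided"`, `"less"`, `"greater"`; the
#'   alternative refers to the first sample relative to the second.
#' @param method `"auto"` (default: exact when possible), or force
#'   `"exact"` / `"normal"`; the exact branch refuses tied data.
#' @return A list of class `rank_sum_result` with `statistic_U`, `p_value`,
#'   `n_a`, `n_b`, `alternative`, `method` (`"exact"` or `"normal"`), and
#'   `degenerate` (`TRUE` when all values are identical, in which case
#'   `p_value` is 1).
#' @export
rank_sum_test <- function(values_a, values_b,
                          alternative = c("two_sided", "less", "greater"),
                          method = c("auto", "exact", "normal")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  if (length(values_a) == 0L || length(values_b) == 0L) {
    stop_param("both samples must be non-empty")
  }
  if (anyNA(values_a) || anyNA(values_b)) stop_param("missing values not allowed")
  n_a <- length(values_a)
  n_b <- length(values_b)
  pooled <- c(values_a, values_b)
  r <- rank(pooled)
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  ties <- table(pooled)
  has_ties <- any(ties > 1L)

  if (length(unique(pooled)) == 1L) {
    return(structure(list(
      statistic_U = u, p_value = 1, n_a = n_a, n_b = n_b,
      alternative = alternative, method = "degenerate", degenerate = TRUE
    ), class = "rank_sum_result"))
  }

  use_exact <- if (method == "auto") !has_ties && n_a * n_b <= 400L
    else method == "exact"
  if (use_exact && has_ties) stop_param("exact method is unavailable with ties")
  if (use_exact) {
    # exact null distribution of U by the standard counting recursion
    pmf <- u_null_pmf(n_a, n_b)
    cdf <- cumsum(pmf)
    p_le <- cdf[u + 1L]
    p_ge <- 1 - if (u >= 1L) cdf[u] else 0
    p <- switch(alternative,
      two_sided = min(1, 2 * min(p_le, p_ge)),
      greater = p_ge,
      less = p_le
    )
    method <- "exact"
  } else {
    mu <- n_a * n_b / 2
    n <- n_a + n_b
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term)
    sigma <- sqrt(sigma2)
    z_ge <- (u - mu - 0.5) / sigma
    z_le <- (u - mu + 0.5) / sigma
    p <- switch(alternative,
      two_sided = {
        z <- (u - mu - sign(u - mu) * 0.5) / sigma
        min(1, 2 * stats::pnorm(abs(z), lower.tail = FALSE))
      },
      greater = stats::pnorm(z_ge, lower.tail = FALSE),
      less = stats::pnorm(z_le)
    )
    method <- "normal"
  }

  structure(list(
    statistic_U = u, p_value = p, n_a = n_a, n_b = n_b,
    alternative = alternative, method = method, degenerate = FALSE
  ), class = "rank_sum_result")
}

# P(U = u) for u = 0..n_a*n_b under the null.  The number of arrangements
# with statistic u is the number of integer partitions of u into at most n_a
# parts, each at most n_b: the coefficient of q^u in the Gaussian binomial
# prod_{i=1..n_a} (1 - q^{n_b+i}) / (1 - q^i).  Computed by exact integer
# polynomial arithmetic (coefficients stay below 2^53 for n_a*n_b <= 400).
u_null_pmf <- function(n_a, n_b) {
  max_u <- n_a * n_b
  coef <- numeric(max_u + 1L)
  coef[1L] <- 1
  for (i in seq_len(n_a)) {
    # multiply by (1 - q^{n_b + i})
    s <- n_b + i
    if (s <= max_u) {
      coef[(s + 1L):(max_u + 1L)] <- coef[(s + 1L):(max_u + 1L)] -
        coef[seq_len(max_u + 1L - s)]
    }
    # divide by (1 - q^i): running sum with stride i (exact division)
    for (u in seq.int(i, max_u)) {
      coef[u + 1L] <- coef[u + 1L] + coef[u - i + 1L]
    }
  }
  coef / sum(coef)
}

#' @export
print.rank_sum_result <- function(x, ...) {
  cat(sprintf("Rank-sum test: U = %g (n = %d, %d), p = %.4g (%s, %s)\n",
              x$statistic_U, x$n_a, x$n_b, x$p_value, x$method,
              x$alternative))
  invisible(x)
}
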