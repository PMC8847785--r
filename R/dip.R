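#' Hartigan's dip statistic
#'
#' The dip of a sample is the smallest sup-norm distance between its
#' empirical CDF and any unimodal CDF (convex up to the mode, concave
#' after).  Large values indicate that no unimodal distribution fits the
#' sample well, i.e. multimodality.  For n distinct values the dip lies in
#' `[1/(2n), 0.25]`; n equally spaced points attain the lower bound.  The
#' statistic is rank-based: any strictly increasing transform of the values
#' leaves it unchanged.
#'
#' Non-finite values (e.g. infinite flexibility scores) are excluded before
#' computation unless `cap_infinite = TRUE`, in which case `+Inf` values are
#' replaced by 1.01 times the largest finite value so they participate as an
#' extreme right tail.
#'
#' @param values Numeric vector; at least 4 finite observations required.
#' @param cap_infinite Replace `+Inf` by `1.01 * max(finite)` instead of
#'   dropping (default `FALSE`).
#' @return The dip statistic (a single number), with attribute
#'   `n_excluded` giving the number of non-finite values dropped.
#' @export
dip_statistic <- function(values, cap_infinite = FALSE) {
  if (!is.numeric(values)) stop_param("'values' must be numeric")
  values <- values[!is.na(values)]
  if (cap_infinite) {
    finite <- values[is.finite(values)]
    if (length(finite) == 0L) stop_param("no finite values to cap against")
    values[values == Inf] <- 1.01 * max(finite)
  }
  n_excluded <- sum(!is.finite(values))
  values <- values[is.finite(values)]
  if (length(values) < 4L) {
    rt_stop("dip statistic requires at least 4 finite observations",
            "restrans_insufficient_data_error")
  }
  out <- .dip_stat_cpp(as.numeric(values))
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Hartigan's dip test for unimodality
#'
#' Compares the observed dip statistic against its null distribution under
#' samples of the same size from the uniform distribution, the standard
#' calibration for the dip test (the uniform is the asymptotically least
#' favourable unimodal null).  The p-value uses the add-one convention
#' \eqn{p = (1 + \#\{dip^{boot} \ge dip\}) / (1 + n_{bootstrap})}, so the
#' smallest attainable p is `1/(n_bootstrap + 1)`.
#'
#' @inheritParams dip_statistic
#' @param n_bootstrap Number of uniform reference samples (default 2000).
#' @param seed Integer seed for the bootstrap draws (required).
#' @param null_dips Optional pre-computed vector of reference dip values for
#'   the same sample size, e.g. from [dip_null_distribution()]; when
#'   supplied the bootstrap is skipped and `seed` is ignored.
#' @return A list of class `dip_result` with `dip_statistic`, `p_value`,
#'   `n_observations` (finite values used), `n_bootstrap`, `n_excluded`.
#' @export
dip_test <- function(values, n_bootstrap = 2000L, seed = NULL,
                     cap_infinite = FALSE, null_dips = NULL) {
  dip <- dip_statistic(values, cap_infinite = cap_infinite)
  n_used <- sum(is.finite(values), na.rm = TRUE) +
    if (cap_infinite) sum(values == Inf, na.rm = TRUE) else 0L
  if (is.null(null_dips)) {
    if (is.null(seed)) stop_param("'seed' is required for the dip bootstrap")
    if (n_bootstrap < 1L) stop_param("'n_bootstrap' must be positive")
    null_dips <- dip_null_distribution(n_used, n_bootstrap, seed)
  }
  p <- (1 + sum(null_dips >= as.numeric(dip) - 1e-15)) / (1 + length(null_dips))
  structure(list(
    dip_statistic = as.numeric(dip),
    p_value = p,
    n_observations = n_used,
    n_bootstrap = length(null_dips),
    n_excluded = attr(dip, "n_excluded")
  ), class = "dip_result")
}

#' Null distribution of the dip statistic for a given sample size
#'
#' Draws `n_bootstrap` samples of size `n` from the uniform distribution and
#' returns their dip statistics.  Useful for reusing one calibration across
#' repeated tests at the same sample size.
#'
#' @param n Sample size.
#' @param n_bootstrap Number of reference samples.
#' @param seed Integer seed.
#' @return Numeric vector of length `n_bootstrap`.
#' @export
dip_null_distribution <- function(n, n_bootstrap = 2000L, seed) {
  with_rng_seed(seed, {
    vapply(seq_len(n_bootstrap),
           function(i) .dip_stat_cpp(stats::runif(n)),
           numeric(1))
  })
}

#' @export
print.dip_result <- function(x, ...) {
  cat(sprintf(
    "Hartigan dip test: dip = %.5f (n = %d), p = %.4g (%d bootstrap samples)\n",
    x$dip_statistic, x$n_observations, x$p_value, x$n_bootstrap
  ))
  invisible(x)
}
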