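#' Divergence of common-garden microbiomes from their field baseline
#'
#' Regresses the Sorensen-Dice dissimilarity of each common-garden-vs-field
#' sample pair on the common-garden member's timepoint (days since arrival),
#' by ordinary least squares.  A positive slope means common-garden samples
#' became more dissimilar from their field population representatives over
#' time.  Each pair is one observation, mirroring a pair-level reading of
#' the design; pairs sharing a sample are therefore not independent, which
#' is documented rather than corrected (see the methods vignette).
#'
#' @param pairs A `data.frame` from [pairwise_comparisons()], restricted by
#'   the caller to within-population common-garden-vs-field pairs (rows with
#'   `comparison_class == "within_population"` and a non-missing
#'   `garden_timepoint`); other rows are dropped with a warning.
#' @param per_population If `TRUE`, fit one regression per population in
#'   addition to the pooled fit.
#' @return A `data.frame` with one row per fit: `population` (`"pooled"` or
#'   a population label), `slope` (dissimilarity per day), `intercept`,
#'   `slope_p_value` (two-sided t-test), `r_squared`, `n_pairs`.
#' @export
divergence_regression <- function(pairs, per_population = TRUE) {
  ok <- pairs$comparison_class == "within_population" &
    !is.na(pairs$garden_timepoint)
  if (!all(ok)) {
    warning(sprintf(
      "dropping %d pair(s) that are not within-population garden-vs-field",
      sum(!ok)
    ))
    pairs <- pairs[ok, , drop = FALSE]
  }
  if (nrow(pairs) == 0L) stop_empty("no eligible pairs for divergence regression")

  fits <- list(fit_divergence(pairs, "pooled"))
  if (per_population) {
    for (pop in sort(unique(pairs$population_a))) {
      sub <- pairs[pairs$population_a == pop, , drop = FALSE]
      fits[[length(fits) + 1L]] <- fit_divergence(sub, pop)
    }
  }
  do.call(rbind, fits)
}

fit_divergence <- function(pairs, label) {
  t <- pairs$garden_timepoint
  y <- pairs$dissimilarity
  if (length(unique(t)) < 2L) {
    stop_design(sprintf(
      "divergence regression for '%s' needs >= 2 distinct timepoints", label
    ))
  }
  fit <- stats::lm(y ~ t)
  sm <- summary(fit)
  data.frame(
    population = label,
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    slope_p_value = unname(sm$coefficients[2L, 4L]),
    r_squared = sm$r.squared,
    n_pairs = length(y),
    stringsAsFactors = FALSE
  )
}
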