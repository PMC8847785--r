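# Classed error conditions so callers and tests can distinguish failure modes.

rt_stop <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "restrans_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

stop_format <- function(msg) rt_stop(msg, "restrans_format_error")
stop_empty  <- function(msg) rt_stop(msg, "restrans_empty_result_error")
stop_param  <- function(msg) rt_stop(msg, "restrans_parameter_error")
stop_design <- function(msg) rt_stop(msg, "restrans_design_error")

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  Keeps permutation tests free of
# hidden global state.
with_rng_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_param("'seed' must be a single non-missing integer")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}
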