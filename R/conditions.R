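# Condition classes shared across the package. The CLI maps them to exit
# codes (validation -> 2, format -> 3, insufficient cycles -> 4).

stop_validation <- function(msg, ..., extra_class = character(0)) {
  stop(structure(
    class = c(extra_class, "gaitq_validation_error", "gaitq_error",
              "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_format <- function(msg, ...) {
  stop(structure(
    class = c("gaitq_format_error", "gaitq_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_insufficient_cycles <- function(msg, ...) {
  stop(structure(
    class = c("gaitq_insufficient_cycles", "gaitq_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
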