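# Internal helpers shared across modules.

# Classed conditions so callers/tests can discriminate failure modes.
stop_segscreen <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "segscreen_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

stop_format <- function(msg) stop_segscreen(msg, "segscreen_format_error")
stop_validation <- function(msg) stop_segscreen(msg, "segscreen_validation_error")
stop_duplicate <- function(msg) stop_segscreen(msg, "segscreen_duplicate_error")
stop_config <- function(msg) stop_segscreen(msg, "segscreen_config_error")
stop_data <- function(msg) stop_segscreen(msg, "segscreen_data_error")
stop_undefined <- function(msg) stop_segscreen(msg, "segscreen_undefined_error")

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library code never perturbs user-level streams.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

is_whole <- function(x, tol = 1e-8) {
  is.finite(x) & abs(x - round(x)) < tol
}

# Canonical treatment key used for joining, ranking tie-breaks and cluster
# leaf labels.
treatment_key <- function(compound_id, concentration, experiment) {
  paste(compound_id, concentration, experiment, sep = "|")
}
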