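# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library calls never clobber a user's random stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort_config("`seed` must be a single integer.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

abort_validation <- function(msg, ...) {
  rlang::abort(msg, class = "longsamgsr_validation_error", ...)
}

abort_parse <- function(msg, ...) {
  rlang::abort(msg, class = "longsamgsr_parse_error", ...)
}

abort_insufficient <- function(msg, ...) {
  rlang::abort(msg, class = "longsamgsr_insufficient_data_error", ...)
}

abort_config <- function(msg, ...) {
  rlang::abort(msg, class = "longsamgsr_config_error", ...)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
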