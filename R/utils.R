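# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed conditions so callers/tests can distinguish failure modes.
opcnn_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "opcnn_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All randomised operations in the package route through this so that a
# single seed argument makes them pure functions of their inputs.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    opcnn_stop("`seed` must be a single finite number", "config_error")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

# Derive a child seed from a base seed and a few stream indices, staying
# inside 32-bit integer range.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed)
  for (i in idx) s <- (s * 69069 + i * 104729 + 1) %% 2147483587
  as.integer(s)
}

check_numeric_vector <- function(x, name, min_len = 1L) {
  if (!is.numeric(x) || length(x) < min_len) {
    opcnn_stop(sprintf("`%s` must be a numeric vector of length >= %d",
                       name, min_len), "dimension_error")
  }
  if (!all(is.finite(x))) {
    opcnn_stop(sprintf("`%s` contains non-finite values", name),
               "dimension_error")
  }
  invisible(x)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
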