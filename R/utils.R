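# Internal helpers shared across modules.

# Derive a reproducible sub-stream seed from a master seed. Offsets are fixed
# per call site so that adding a new consumer never reshuffles existing ones.
substream <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483629L)
}

# Evaluate `expr` under a fixed RNG state without disturbing the caller's.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == as.integer(x)
}

is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

stop_config <- function(msg) {
  abort(msg, class = "droughtgs_config_error")
}

stop_input <- function(msg) {
  abort(msg, class = "droughtgs_input_error")
}

check_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0L) {
    stop_input(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(data)
}

# Symmetric positive-definiteness probe via Cholesky.
is_positive_definite <- function(m) {
  inherits(try(chol(m), silent = TRUE), "matrix")
}
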