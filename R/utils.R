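# internal helpers shared across modules

# classed errors so callers/tests can condition on the failure kind
abort <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "trscore_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1))
  ))
}

warn <- function(msg, class) {
  warning(structure(
    class = c(class, "trscore_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x)
}

is_prob <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x <= 1

# one RNG stream per pipeline stage, derived from a single master seed by
# fixed integer offsets (kept < 2^31)
derive_seed <- function(seed, offset) {
  s <- (as.double(seed) + as.double(offset)) %% 2147483647
  as.integer(s)
}

# row-wise means/sds without matrixStats
row_sds <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  sqrt(rowSums((x - m)^2) / (n - 1))
}
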