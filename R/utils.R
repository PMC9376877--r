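#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Row/column indices of the strict upper triangle of an N x N matrix,
# in column-major order (matching `upper.tri`).
upper_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  list(i = idx[, 1L], j = idx[, 2L])
}

# Deterministic child seed: keeps derived seeds inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647L)
}

stop_mxad <- function(...) stop(sprintf(...), call. = FALSE)
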