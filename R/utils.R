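# Internal helpers shared across modules.

#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
NULL

# Run `code` under a fixed RNG state when `seed` is given, leaving the
# caller's RNG untouched; with seed = NULL the global stream is used
# (and advanced) as usual.
with_seed_or_stream <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
    withr::with_seed(as.integer(seed), code)
  }
}

# Upper-triangle (i < j) values of a square matrix, column-major order.
upper_tri_values <- function(m) m[upper.tri(m)]

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min),
          class = "phylospace_parameter_error")
  }
  invisible(as.integer(x))
}
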