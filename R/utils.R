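# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed without disturbing the caller's RNG
# stream. All user-facing randomness in the package funnels through this, so
# identical (arguments, seed) pairs give bit-identical results.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
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

# Derive a child seed from a base seed and an index; keeps independent
# randomness streams (per ensemble trial, per component, per whale draw)
# reproducible while staying inside 32-bit integer range.
child_seed <- function(seed, k) {
  (as.numeric(seed) * 1000003 + 7919 * as.numeric(k)) %% 2147483647
}

check_numeric_vector <- function(x, name, min_len = 1) {
  if (!is.numeric(x)) {
    abort(sprintf("`%s` must be numeric, not %s.", name, class(x)[1]))
  }
  if (length(x) < min_len) {
    abort(sprintf("`%s` must have at least %d values (got %d).",
                  name, min_len, length(x)))
  }
  if (anyNA(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` contains missing or non-finite values.", name))
  }
  invisible(x)
}

check_equal_length <- function(x, y, xname = "predicted", yname = "observed") {
  if (length(x) != length(y)) {
    abort(sprintf("`%s` (length %d) and `%s` (length %d) must have equal length.",
                  xname, length(x), yname, length(y)))
  }
  invisible(TRUE)
}
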