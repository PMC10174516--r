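#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the global RNG to `seed`, evaluates `expr`, and restores the previous
#' RNG state on exit, so seeded package operations do not disturb the caller's
#' random stream.
#'
#' @param seed integer scalar seed (must be < 2^31).
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_rng_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  expr
}

# clamp a matrix/vector elementwise into [lower, upper] (recycled per column)
clamp <- function(x, lower, upper) {
  pmin(pmax(x, lower), upper)
}

# clamp rows of an n x d matrix to per-dimension bounds
clamp_rows <- function(x, lower, upper) {
  lo <- matrix(lower, nrow(x), ncol(x), byrow = TRUE)
  hi <- matrix(upper, nrow(x), ncol(x), byrow = TRUE)
  pmin(pmax(x, lo), hi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# format doubles so that read.csv() recovers them to full precision
format_full <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else as.character(x)
}

# derive a child seed from a base seed and an index, kept inside 32-bit range
derive_seed <- function(seed_base, index) {
  s <- bitwXor(as.integer(seed_base), as.integer(index) * 2654435L)
  abs(s %% 2147483647L)
}
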