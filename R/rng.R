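#' Evaluate an expression under a local, explicit random seed
#'
#' Every stochastic operation in the package takes a seed argument and runs
#' under this helper, so results are reproducible bit-for-bit and the caller's
#' global RNG state is never disturbed.
#'
#' @param seed Integer scalar seed.
#' @param expr Expression to evaluate.
#' @return Value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (length(seed) != 1L || !is.finite(seed) || seed != round(seed)) {
    stop("seed must be a single integer", call. = FALSE)
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
  expr
}

# Derive a stream of sub-seeds from a master seed, staying within 32-bit
# integer range.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
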