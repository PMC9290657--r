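#' Evaluate an expression under a temporary RNG seed
#'
#' All randomness in ltrcnet flows through explicit integer seeds; no
#' function leaves the global random state altered. `with_seed()` saves the
#' caller's `.Random.seed`, seeds the generator, evaluates `expr`, and
#' restores the previous state on exit.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (is.null(old)) {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  } else {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## Derive a stream of child seeds from one master seed, so that independent
## components (design, survival, censoring, entry, ...) never share draws.
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
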