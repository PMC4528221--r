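#' @keywords internal
"_PACKAGE"

## Seed handling: every stochastic routine takes an explicit integer seed and
## restores the caller's RNG state on exit, so whole-pipeline runs are
## reproducible from a single top-level seed.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's `.Random.seed`, seeds the generator, evaluates `expr`,
#' and restores the previous state on exit.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
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

#' Derive a stage-specific seed from a top-level seed
#'
#' Deterministic mixing of a base seed with a stage tag so that independent
#' pipeline stages (simulation, fold splitting, permutations, ...) use
#' decorrelated but reproducible RNG streams. The result is always a positive
#' 32-bit integer.
#'
#' @param seed Integer base seed.
#' @param tag Character stage tag, or an integer offset.
#' @return A positive integer seed below 2^31.
#' @export
derive_seed <- function(seed, tag) {
  h <- if (is.character(tag)) sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag))) else as.numeric(tag)
  mixed <- (as.numeric(seed) * 48271 + h * 16807 + 12345) %% 2147483647
  as.integer(max(1, mixed))
}

#' Round half away from zero
#'
#' Display rounding used for percentage tables (`round()` in R rounds half to
#' even, which does not match conventional reporting of accuracies).
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector.
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

## internal argument checks -------------------------------------------------

stop_invalid <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) stop_invalid(sprintf("`%s` must be > 0", name))
  if (nonneg && x < 0) stop_invalid(sprintf("`%s` must be >= 0", name))
  invisible(x)
}
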