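#' Evaluate an expression under a local RNG seed
#'
#' All stochastic operations in the package take an explicit integer seed and
#' route their randomness through this helper, which seeds the generator for
#' the duration of the expression and then restores the caller's random state.
#' No function in the package touches global random state as a side effect.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
withRNG <- function(seed, code) {
  if (length(seed) != 1L || !is.numeric(seed) || is.na(seed))
    stop("'seed' must be a single non-missing integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# clamp correlations away from +/-1 so the Fisher z-transform stays finite;
# tanh(atanh(.)) returns the value unchanged to machine precision
.clampR <- function(r) pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)

.assertCount <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != floor(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min))
  as.integer(x)
}

.assertFraction <- function(x, name, maxOpen = FALSE) {
  ok <- length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 &&
    (if (maxOpen) x < 1 else x <= 1)
  if (!ok) stop(sprintf("'%s' must be a probability in [0,%s", name,
                        if (maxOpen) "1)" else "1]"))
  as.numeric(x)
}
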