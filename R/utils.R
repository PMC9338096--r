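#' @keywords internal
#' @useDynLib forcepoint, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All randomized operations in the package funnel through this so that a
# single integer seed makes a whole pipeline reproducible.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-stream seed for item `i` of a run seeded with `seed`.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) %% 1e6) * 2039L + 7919 * as.double(i)) %% 2147483611L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fp <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "fp_error")))
}
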