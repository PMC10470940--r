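# Internal helpers shared across modules.

sigmoid <- function(x) 1 / (1 + exp(-x))

leakyRelu <- function(x, slope = 0.01) ifelse(x > 0, x, slope * x)

leakyReluGrad <- function(x, slope = 0.01) ifelse(x > 0, 1, slope)

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded package operations do not
#' perturb the caller's random stream.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic 31-bit hash of an integer vector (FNV-style, double arithmetic
# kept below 2^53 so the result is exact on every platform).
hashIntVec <- function(v) {
  h <- 2166136261
  for (x in v) {
    h <- (h * 31 + (x %% 2147483647)) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopIfNot <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
}
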