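#' @importFrom methods new validObject is slot
#' @importFrom stats rnorm rbinom rpois runif rbeta var sd cor lm resid
#'   model.matrix setNames dhyper optim complete.cases aggregate quantile
#' @importFrom utils head tail write.table read.table
NULL

## Breed labels used throughout: paternal sire line S, maternal dam lines
## LR (Landrace-type) and LW (Large White-type).
BREEDS <- c("S", "LR", "LW")

#' Derive independent child seeds from one master seed
#'
#' All stochastic functions in the package draw their randomness from a
#' single integer seed; stages split the master seed into per-stage child
#' seeds with this helper so that stages are reproducible in isolation.
#'
#' @param seed Integer master seed.
#' @param n Number of child seeds required.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
deriveSeeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_msg <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

## symmetrise a numeric matrix (guards tiny asymmetries from BLAS)
symmpart <- function(M) (M + t(M)) / 2
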