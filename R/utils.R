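# Internal helpers shared across modules.

#' @importFrom stats cor var sd quantile rnorm runif rbinom predict
#' @importFrom methods new validObject is slot
#' @importFrom utils read.table write.table head
NULL

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. All exported stochastic entry points funnel through this
# so a single user seed makes every run reproducible.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic expansion of one top-level seed into per-component seeds.
# Components are named so logs can record the expansion; result < 2^31.
derive_seed <- function(seed, component) {
  offsets <- c(
    simulate = 11L, trait = 23L, splits = 37L, repgeno = 53L,
    menet = 71L, transfer = 89L, attribute = 101L, triplets = 113L,
    scratch = 131L, init = 149L, batch = 167L
  )
  off <- offsets[[component]]
  if (is.null(off)) off <- 997L
  (as.integer(seed) %% 1048576L) * 1021L + off
}

# Numerically stable softplus log(1 + exp(x)), elementwise.
softplus <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
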