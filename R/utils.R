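#' @useDynLib qpactoed, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods as is new
#' @importFrom stats rnorm runif uniroot
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derived sub-stream seeds (kept below 2^31): `stream` separates uses
# (prior draw vs. noise draw), `i` indexes the sample so sample i is
# reproducible independently of how many samples are requested.
derive_seed <- function(seed, i, stream = 0L) {
  s <- (as.double(seed) * 48271 + as.double(i) * 7919 + as.double(stream) * 104729)
  as.integer(s %% 2147483629) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dim <- function(what, expected, got) {
  stop(sprintf("%s: expected length %d, got %d", what, expected, got), call. = FALSE)
}
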