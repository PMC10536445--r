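# Internal helpers shared across modules.

# Evaluate `expr` under `set.seed(seed)` without disturbing the caller's RNG
# stream. `seed = NULL` leaves the ambient stream untouched.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else {
        suppressWarnings(rm(".Random.seed", envir = globalenv()))
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# keep probabilities away from {0,1} before taking logs
clamp_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

# Glorot/Xavier uniform initialization; fans may differ from dim for convs
glorot <- function(fan_in, fan_out, dim = c(fan_in, fan_out)) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dim), -lim, lim), dim = dim)
}

zeros_like <- function(a) {
  if (is.list(a)) return(lapply(a, zeros_like))
  if (is.null(dim(a))) numeric(length(a)) else array(0, dim = dim(a))
}

count_params <- function(a) {
  if (is.list(a)) return(sum(vapply(a, count_params, numeric(1))))
  length(a)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
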