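# internal numeric helpers

.datatable.aware <- TRUE

# numerically stable log(1 + exp(x))
softplus <- function(x) {
  ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
}

# inverse of softplus; defined for y > 0
softplus_inv <- function(y) {
  stopifnot(all(y > 0))
  ifelse(y > 30, y, log(expm1(pmax(y, 1e-12))))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

log2e <- 1 / log(2)

# run `expr` under a fixed RNG seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic per-unit seed derivation, kept inside 32-bit integer range
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483647)
}

# reduce an angle to [0, pi)
mod_pi <- function(x) {
  y <- x %% pi
  ifelse(y >= pi, y - pi, y)
}
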