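# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards, so seeded generators are pure functions of their config.
with_seed <- function(seed, expr) {
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

# Derive a reproducible sub-seed (< 2^31) from a base seed and a stream name.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Acute angle (degrees, in [0, 90]) between undirected 2D directions.
acute_angle <- function(u, v) {
  nu <- sqrt(rowSums(u^2))
  nv <- sqrt(rowSums(v^2))
  d <- abs(rowSums(u * v)) / (nu * nv)
  d <- pmin(pmax(d, -1), 1)
  acos(d) * 180 / pi
}
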