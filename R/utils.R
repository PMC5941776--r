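# Internal helpers shared across modules.

# Deterministic 32-bit seed mixing so every sample / run / fold gets its own
# reproducible RNG stream derived from one master seed. Kept below 2^31.
mix_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) + 1
  x <- (s * 48271) %% 2147483647
  x <- (x + as.double(index) * 2654435761) %% 2147483647
  x <- (x * 48271) %% 2147483647
  as.integer(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.
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

stopf <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "scmhand_error")))
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}
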