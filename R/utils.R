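# Internal helpers shared across modules.

# Evaluate expr under a local RNG state so generators are pure functions of
# their seed: the caller's .Random.seed is saved and restored.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

# round-half-up to the nearest integer (R's round() is round-half-even)
roundHalfUp <- function(x) floor(x + 0.5)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
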