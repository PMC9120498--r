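# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched. All exported stochastic operations route their
# randomness through this, so a fixed seed gives bit-identical output.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a stage seed from a root seed, kept inside 32-bit integer range.
deriveSeed <- function(seed, stage) {
  (as.integer(seed) * 1000L + as.integer(stage)) %% .Machine$integer.max
}

stopIfNot <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

# Single positive integer check used by the simulators.
checkCount <- function(x, name, min = 1L) {
  stopIfNot(length(x) == 1L && is.finite(x) && x >= min && x == floor(x),
            "'%s' must be a single integer >= %d", name, min)
  as.integer(x)
}
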