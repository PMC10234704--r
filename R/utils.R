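# Internal helpers shared across modules.

# Run code with a temporarily fixed RNG state, restoring (or removing) the
# global .Random.seed afterwards so callers' RNG streams are untouched.
with_local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-stage seed from one global seed so toggling one pipeline stage
# does not shift another stage's draws. Kept strictly below 2^31.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  m <- 2147483647
  as.integer(((as.numeric(seed) %% m) * 48271 + as.numeric(stream)) %% m)
}

# Percentage rounding to match half-up table formatting (e.g. 99.7361 -> 99.74).
round_half_up <- function(x, digits = 2) {
  pow <- 10^digits
  sign(x) * floor(abs(x) * pow + 0.5) / pow
}

`%||%` <- function(a, b) if (is.null(a)) b else a
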