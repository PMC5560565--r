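# Small shared helpers.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# clamp to [lo, hi]
.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# smoothstep: 0 at u <= 0, 1 at u >= 1, C1 in between
.smoothstep <- function(u) {
  u <- .clamp(u, 0, 1)
  u * u * (3 - 2 * u)
}
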