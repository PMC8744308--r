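`%||%` <- function(x, y) if (is.null(x)) y else x

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Derive a per-stage RNG seed from the run seed (Lehmer step + stage offset,
# kept inside 32-bit integer range so stages are individually reproducible).
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + stage) %% 2147483647)
}

# Run an expression under a local RNG seed without disturbing the caller's
# RNG state. seed = NULL leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      suppressWarnings(rm(".Random.seed", envir = globalenv())),
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}
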