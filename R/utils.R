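`%||%` <- function(a, b) if (is.null(a)) b else a

# Run expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  env <- globalenv()
  has_old <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  expr
}

# Deterministic child seed, kept inside 32-bit integer range.
child_seed <- function(seed, k) {
  (as.integer(seed) + 7919L * as.integer(k)) %% 2147483629L
}
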