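# Small internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library functions do not perturb user analyses.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Deterministically derive a stream of sub-seeds from one master seed,
# keeping every value a valid 32-bit R integer.
derive_seeds <- function(seed, n) {
  (as.numeric(seed) * 48271 + 7919 * seq_len(n)) %% 2147483647 + 1
}

`%||%` <- function(a, b) if (is.null(a)) b else a
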