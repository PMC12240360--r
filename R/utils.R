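# internal RNG helpers: all stochastic stages run under locally scoped seeds
# so that no function disturbs the caller's RNG state.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% 2147483647))
  }
  force(expr)
}

# deterministic per-replicate seed from (base_seed, parameter draw, initial
# draw); injective for draw indices below ~65 each, always below 2^31
replicate_seed <- function(base_seed, param_idx, init_idx = 0L) {
  (as.numeric(base_seed) %% 2100000000 + 1009 * param_idx + 31 * init_idx) %%
    2147483647
}
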