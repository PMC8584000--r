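# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG
# state afterwards so seeded helpers do not perturb the session stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(code)
}

# Derive a stream of child seeds from one master seed (keeps every seed
# a valid 32-bit integer).
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 2654435) %% 2147483647)
}
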