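# Shared fixtures and independent re-implementations used as oracles.

# a small, structurally varied set of hand-picked molecules
fixture_smiles <- function() {
  c(
    "CCO", "c1ccccc1", "CC(=O)Nc1ccc(O)cc1", "CC(=O)Oc1ccccc1C(=O)O",
    "c1ccc2c(c1)ncc(n2)N", "CCN(CC)C(=O)c1ccccc1", "Cc1ccc(C)cc1",
    "Cc1cccc(C)c1", "O=C(Nc1ccccc1)Nc1ccncc1", "c1ccsc1", "C1CCNCC1",
    "CC(C)Cc1ccc(cc1)C(C)C(=O)O", "Oc1ccc(Cl)cc1", "FC(F)(F)c1ccccc1",
    "CCCCCCCC", "CN1CCC[C@H]1c1cccnc1"
  )
}

# fixture reference molecule: a urea-linked heteroaryl scaffold, so no
# external lookup is needed anywhere in the suite
fixture_reference <- function() "O=C(Nc1ccccc1)Nc1ccncc1"

# a deterministic synthetic pool, memoized across test files
pool_cache <- new.env(parent = emptyenv())
fixture_pool <- function(n = 120, seed = 7) {
  key <- paste0("pool_", n, "_", seed)
  if (is.null(pool_cache[[key]])) {
    pool_cache[[key]] <- generate_pool(n, rng_seed = seed)
  }
  pool_cache[[key]]
}

# independent Tanimoto from on-bit index sets
brute_tanimoto <- function(bits_a, bits_b) {
  u <- length(union(bits_a, bits_b))
  if (u == 0) return(0)
  length(intersect(bits_a, bits_b)) / u
}

# independent objective recomputation from parts
brute_objective <- function(d_raw, penalty, q, s, wd, wq, ws) {
  wd * (d_raw + penalty) - wq * q - ws * s
}

# brute-force re-implementation of the two bank-replacement rules,
# written against the rule statement (not the package code): children in
# order; most-similar member; >= cutoff -> challenge that member, else
# challenge the worst; strict improvement required
brute_update_bank <- function(bank_smiles, bank_r, bank_bits,
                              child_smiles, child_r, child_bits, cutoff) {
  for (k in seq_along(child_smiles)) {
    if (child_smiles[k] %in% bank_smiles) next
    sims <- vapply(bank_bits, function(b) brute_tanimoto(b, child_bits[[k]]),
                   numeric(1))
    j <- which.max(sims)
    if (sims[j] < cutoff) j <- which.max(bank_r)
    if (child_r[k] < bank_r[j]) {
      bank_smiles[j] <- child_smiles[k]
      bank_r[j] <- child_r[k]
      bank_bits[[j]] <- child_bits[[k]]
    }
  }
  list(smiles = bank_smiles, r = bank_r)
}
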