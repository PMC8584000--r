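# CSA optimizer: bank bookkeeping, operators, the bank-update rules
# (against a brute-force oracle) and the full annealing loop.

oracle <- oracle_scorer()
obj_cfg_fix <- function() objective_config(reference = fixture_reference())

test_that("config arithmetic encodes 20 crossover + 60 mutant children", {
  cfg <- csa_config()
  expect_equal(cfg$n_bank, 500L)
  expect_equal(cfg$n_seed, 300L)
  expect_equal(cfg$n_crossover_children, 20L)
  expect_equal(cfg$n_children_per_seed, 80L)
  expect_equal(cfg$max_iterations, 100L)
  expect_error(csa_config(n_seed = 10, n_bank = 5), "n_seed")
  expect_error(csa_config(cutoff_factor = 0), "cutoff_factor")
})

test_that("bank initialization samples, scores, dedupes and errors", {
  pool <- fixture_pool(40)
  cfg <- csa_config(n_bank = 20, n_seed = 5, rng_seed = 2)
  bank <- init_bank(pool, cfg, oracle, obj_cfg_fix())
  expect_length(bank$smiles, 20L)
  expect_length(unique(bank$smiles), 20L)
  expect_false(any(bank$used))
  expect_equal(bank$similarity_cutoff, bank$avg_pairwise_similarity / 2)
  # determinism
  bank2 <- init_bank(pool, cfg, oracle, obj_cfg_fix())
  expect_identical(bank$smiles, bank2$smiles)
  # duplicates collapse before sampling; exact-size pool is kept whole
  cfg10 <- csa_config(n_bank = 10, n_seed = 2, rng_seed = 2)
  dup_pool <- rep(fixture_pool(10), 3)
  bank3 <- init_bank(dup_pool, cfg10, oracle, obj_cfg_fix())
  expect_setequal(bank3$smiles, canonicalize_smiles(fixture_pool(10)))
  expect_error(init_bank(fixture_pool(10), cfg, oracle, obj_cfg_fix()),
               "n_bank")
})

test_that("average bank similarity equals the brute-force pairwise mean", {
  mols <- fixture_pool(5)
  avg <- average_bank_similarity(mols)
  sims <- c()
  for (i in 1:4) for (j in (i + 1):5) {
    sims <- c(sims, tanimoto_similarity(mols[i], mols[j]))
  }
  expect_equal(avg, mean(sims), tolerance = 1e-12)
  expect_error(average_bank_similarity(mols[1]), "at least 2")
})

test_that("seed selection takes the best unused and resets on exhaustion", {
  pool <- fixture_pool(30)
  cfg <- csa_config(n_bank = 12, n_seed = 5, rng_seed = 3)
  bank <- init_bank(pool, cfg, oracle, obj_cfg_fix())
  sel1 <- select_seeds(bank, cfg)
  best5 <- order(bank$objective$r_total, bank$smiles,
                 method = "radix")[1:5]
  expect_setequal(sel1$seed_idx, best5)
  expect_true(all(sel1$bank$used[sel1$seed_idx]))
  # second and third draws exhaust the bank (12 members, 5 per draw);
  # the third resets flags and restarts from the best
  sel2 <- select_seeds(sel1$bank, cfg)
  expect_length(intersect(sel1$seed_idx, sel2$seed_idx), 0L)
  sel3 <- select_seeds(sel2$bank, cfg)
  expect_setequal(sel3$seed_idx, best5)
})

test_that("crossover produces valid children deterministically", {
  set.seed(11)
  child <- crossover("CCCCCC", "c1ccccc1CN")
  expect_false(is.na(child))
  expect_identical(canonicalize_smiles(child), child)
  # determinism under a fixed RNG state across many fixture pairs
  pool <- fixture_pool(20)
  set.seed(42)
  pairs <- cbind(sample(pool, 50, TRUE), sample(pool, 50, TRUE))
  run_once <- function() {
    set.seed(99)
    apply(pairs, 1L, function(p) crossover(p[1], p[2], max_attempts = 10))
  }
  expect_identical(run_once(), run_once())
  # zero attempts -> no child
  expect_true(is.na(crossover("CCO", "CCN", max_attempts = 0)))
})

test_that("mutations parse, differ from the parent, and respect limits", {
  pool <- fixture_pool(15)
  set.seed(7)
  for (kind in c("replace", "remove", "add")) {
    for (s in pool) {
      m <- mutate_smiles(s, kind, max_attempts = 20)
      if (!is.na(m)) {
        expect_identical(canonicalize_smiles(m), m)
        expect_false(identical(m, s))
      }
    }
  }
  # removing the only atom cannot give a valid molecule
  set.seed(1)
  expect_true(is.na(mutate_smiles("C", "remove")))
  # removal from ethanol leaves a valid 2-heavy-atom molecule
  set.seed(1)
  r <- mutate_smiles("CCO", "remove")
  expect_false(is.na(r))
  expect_equal(nrow(dockgen:::smiles_atoms(r)), 2L)
})

test_that("child generation reaches the 20 + 60 = 80 target on robust seeds", {
  cfg <- csa_config(n_bank = 10, n_seed = 2, rng_seed = 5,
                    max_operator_attempts = 50)
  # flexible acyclic parents: operators nearly always succeed
  seed_mol <- "CCOCCNCCOCC"
  partners <- c("CCOCCOCCOCC", "CCNCCCCCCN", "CCCCOCCCCC", "CCCSCCCCC")
  set.seed(31)
  kids <- generate_children(seed_mol, partners, cfg)
  expect_true(all(!is.na(canonicalize_smiles(kids))))
  # all 80 slots fill on these flexible parents; canonical deduplication
  # may collapse a handful of coincident children
  expect_lte(length(kids), 80L)
  expect_gte(length(kids), 60L)
  # crossover stage alone yields the 20 slots
  set.seed(31)
  cross <- vapply(1:20, function(i) {
    p <- partners[sample.int(length(partners), 1L)]
    if (runif(1) < 0.5) dockgen:::crossover_raw(p, seed_mol, 50)
    else dockgen:::crossover_raw(seed_mol, p, 50)
  }, character(1))
  expect_equal(sum(!is.na(cross)), 20L)
})

test_that("bank update matches the brute-force replacement rules", {
  pool <- fixture_pool(80)
  cfg <- csa_config(n_bank = 8, n_seed = 2, rng_seed = 1)
  obj_cfg <- obj_cfg_fix()
  set.seed(17)
  for (rep in 1:200) {
    nb <- sample(3:8, 1)
    nc <- sample(1:6, 1)
    members <- sample(pool, nb)
    children <- sample(pool, nc)
    cfg_b <- csa_config(n_bank = nb, n_seed = 2, rng_seed = rep)
    bank <- init_bank(members, cfg_b, oracle, obj_cfg)
    updated <- update_bank(bank, children, oracle, obj_cfg)

    child_obj <- evaluate_objective(setdiff(children, bank$smiles),
                                    oracle, obj_cfg)
    brute <- brute_update_bank(
      bank$smiles, bank$objective$r_total,
      dockgen:::cached_pathfp(bank$smiles),
      child_obj$smiles, child_obj$r_total,
      dockgen:::cached_pathfp(child_obj$smiles),
      bank$similarity_cutoff
    )
    expect_identical(updated$smiles, brute$smiles)
    expect_equal(updated$objective$r_total, brute$r, tolerance = 1e-12)
    expect_length(updated$smiles, nb)
    expect_length(unique(updated$smiles), nb)
  }
})

test_that("worse children leave the bank unchanged; better dissimilar ones evict the worst", {
  obj_cfg <- obj_cfg_fix()
  cfg <- csa_config(n_bank = 6, n_seed = 2, rng_seed = 4)
  bank <- init_bank(fixture_pool(20)[1:6], cfg, oracle, obj_cfg)
  # a child scored worse than everything cannot enter
  bad_scorer <- function(s) rep(1000, length(s))
  bank_obj <- bank$objective
  upd <- update_bank(bank, "c1ccncc1CNC(=O)C", bad_scorer, obj_cfg)
  expect_identical(upd$smiles, bank$smiles)
  # a dominating child dissimilar to everyone evicts the worst member
  good_scorer <- function(s) rep(-1e6, length(s))
  worst <- which.max(bank_obj$r_total)
  upd2 <- update_bank(bank, "IC(I)C(I)S", good_scorer, obj_cfg)
  expect_false(bank$smiles[worst] %in% upd2$smiles)
  expect_true(canonicalize_smiles("IC(I)C(I)S") %in% upd2$smiles)
})

test_that("cutoff annealing is multiplicative with a floor", {
  cfg <- csa_config(n_bank = 5, n_seed = 2, cutoff_factor = 0.9,
                    cutoff_floor = 0.1, rng_seed = 1)
  bank <- init_bank(fixture_pool(10)[1:5], cfg, oracle, obj_cfg_fix())
  bank$similarity_cutoff <- 0.4
  for (i in 1:3) bank <- anneal_cutoff(bank, cfg)
  expect_equal(bank$similarity_cutoff, 0.4 * 0.9^3, tolerance = 1e-12)
  for (i in 1:30) bank <- anneal_cutoff(bank, cfg)
  expect_equal(bank$similarity_cutoff, 0.1)
  # default factor 1: cutoff constant
  cfg1 <- csa_config(n_bank = 5, n_seed = 2, rng_seed = 1)
  bank1 <- init_bank(fixture_pool(10)[1:5], cfg1, oracle, obj_cfg_fix())
  c0 <- bank1$similarity_cutoff
  expect_equal(anneal_cutoff(bank1, cfg1)$similarity_cutoff, c0)
})

test_that("a short CSA run improves monotonically and reproduces exactly", {
  pool <- fixture_pool(60)
  cfg <- csa_config(n_bank = 15, n_seed = 5, max_iterations = 3,
                    rng_seed = 21)
  res <- run_csa(pool, cfg, oracle, obj_cfg_fix())
  expect_equal(res$trajectory$iteration, 0:3)
  expect_true(all(diff(res$trajectory$best_r) <= 1e-12))
  expect_lte(min(res$bank$objective$r_total), res$trajectory$best_r[1])
  expect_length(unique(res$bank$smiles), 15L)
  expect_false(anyNA(canonicalize_smiles(res$bank$smiles)))
  res2 <- run_csa(pool, cfg, oracle, obj_cfg_fix())
  expect_identical(res$bank$smiles, res2$bank$smiles)
  expect_identical(res$trajectory, res2$trajectory)
})
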