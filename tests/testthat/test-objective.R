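# Objective function: penalty rules, linear identity, ranking.

test_that("penalty triggers on either Lipinski violation and on radicals", {
  cfg <- objective_config(reference = fixture_reference())
  # drug-like molecule: no penalty
  expect_equal(penalty_for("CC(=O)Nc1ccc(O)cc1", cfg), 0)
  # logP > 5 alone (MW < 500): OR semantics trigger the penalty
  prof_alkane <- lipinski_profile("CCCCCCCCCCCCCCCCCCCC")
  expect_gt(prof_alkane$logp, 5)
  expect_lt(prof_alkane$mw, 500)
  expect_equal(penalty_for("CCCCCCCCCCCCCCCCCCCC", cfg), 1000)
  # MW > 500 alone (polar peptide-like chain: heavy but hydrophilic)
  big <- paste0("CC(=O)", paste(rep("NC(C)C(=O)", 8), collapse = ""), "O")
  prof_big <- lipinski_profile(big)
  expect_gt(prof_big$mw, 500)
  expect_lt(prof_big$logp, 5)
  expect_equal(penalty_for(big, cfg), 1000)
  # radical: separate 1000
  expect_equal(penalty_for("[CH3]", cfg), 1000)
  expect_error(penalty_for("C1CC", cfg), "invalid")
})

test_that("objective equals the hand-computed linear combination", {
  cfg <- objective_config(omega_d = 0.03, omega_q = 1, omega_s = 1,
                          reference = fixture_reference())
  # fixed scorer so the docking term is exactly -8.5
  scorer <- function(smiles) rep(-8.5, length(smiles))
  mol <- "CC(=O)Nc1ccc(O)cc1"
  obj <- evaluate_objective(mol, scorer, cfg)
  expect_equal(obj$d_raw, -8.5)
  expect_equal(obj$penalty, 0)
  expect_equal(obj$r_total, 0.03 * (-8.5) - obj$q - obj$s, tolerance = 1e-12)
  # hand value with q = 0.9, s = 0.8 would be -1.955; check the same
  # arithmetic with the package-computed q and s
  expect_equal(dockgen:::oracle_energy(300, 2, 1, 3, 2.0), -5.9)
  expect_equal(0.03 * (-8.5) - 0.9 - 0.8, -1.955)

  # zero weights: objective vanishes identically
  cfg0 <- objective_config(omega_d = 0, omega_q = 0, omega_s = 0,
                           reference = fixture_reference())
  expect_equal(evaluate_objective(mol, scorer, cfg0)$r_total, 0)

  # penalty linearity: a penalized molecule exceeds its unpenalized
  # value by exactly omega_d * 1000
  alkane <- "CCCCCCCCCCCCCCCCCCCC"
  obj_pen <- evaluate_objective(alkane, scorer, cfg)
  unpen <- 0.03 * (-8.5) - obj_pen$q - obj_pen$s
  expect_equal(obj_pen$r_total - unpen, 0.03 * 1000, tolerance = 1e-12)
})

test_that("doubling omega_q shifts the objective by exactly -q", {
  cfg1 <- objective_config(omega_q = 1, reference = fixture_reference())
  cfg2 <- objective_config(omega_q = 2, reference = fixture_reference())
  scorer <- oracle_scorer()
  mols <- fixture_pool(20)
  o1 <- evaluate_objective(mols, scorer, cfg1)
  o2 <- evaluate_objective(mols, scorer, cfg2)
  expect_equal(o2$r_total - o1$r_total, -o1$q, tolerance = 1e-12)
})

test_that("ranking is ascending, tie-stable and matches brute force", {
  cfg <- objective_config(reference = fixture_reference())
  scorer <- oracle_scorer()
  mols <- fixture_pool(50)
  ranked <- rank_molecules(mols, scorer, cfg)
  expect_equal(nrow(ranked), 50L)
  expect_true(!is.unsorted(ranked$r_total))

  # independent recomputation of the linear combination and ordering
  obj <- evaluate_objective(mols, scorer, cfg)
  brute_r <- brute_objective(obj$d_raw, obj$penalty, obj$q, obj$s,
                             cfg$omega_d, cfg$omega_q, cfg$omega_s)
  expect_equal(obj$r_total, brute_r, tolerance = 1e-12)
  brute_order <- obj$smiles[order(brute_r, obj$smiles, method = "radix")]
  expect_identical(ranked$smiles, brute_order)

  # empty input
  expect_equal(nrow(rank_molecules(character(0), scorer, cfg)), 0L)
})

test_that("penalized molecules never reach the top of a mixed ranking", {
  cfg <- objective_config(reference = fixture_reference())
  scorer <- oracle_scorer()
  clean <- fixture_pool(15)
  dirty <- c("CCCCCCCCCCCCCCCCCCCC", "[CH2]CCc1ccccc1")
  ranked <- rank_molecules(c(dirty, clean), scorer, cfg)
  expect_false(any(ranked$smiles[1:10] %in%
                     canonicalize_smiles(dirty)))
  expect_true(all(ranked$penalty[1:10] == 0))
})
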