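# Featurization: canonicalization, descriptors, fingerprints, the 2232
# feature-vector layout, Tanimoto similarity and the Lipinski profile.

test_that("canonicalization is idempotent and collapses equivalent inputs", {
  expect_identical(canonicalize_smiles("OCC"), canonicalize_smiles("CCO"))
  aromatic <- canonicalize_smiles("C1=CC=CC=C1")
  expect_identical(canonicalize_smiles("c1ccccc1"), aromatic)

  # idempotence over a structurally varied set, via the raw (unmemoized)
  # converter so the check exercises the toolkit, not the cache
  for (s in c(fixture_smiles(), fixture_pool(40))) {
    c1 <- dockgen:::ob_canonicalize_one(s)
    expect_false(is.na(c1))
    expect_identical(dockgen:::ob_canonicalize_one(c1), c1)
  }
})

test_that("invalid SMILES yield NA in batch mode and errors in strict mode", {
  expect_true(is.na(canonicalize_smiles("C1CC")))  # unclosed ring
  out <- canonicalize_smiles(c("CCO", "C1CC", "c1ccccc1"))
  expect_identical(is.na(out), c(FALSE, TRUE, FALSE))
  expect_error(canonicalize_smiles("C1CC", strict = TRUE), "unparseable")

  m <- molecule("C1CC")
  expect_false(m$valid)
  expect_true(is.na(m$smiles_canonical))
  expect_error(compute_descriptors("C1CC"), "invalid")
  expect_error(qed_score("C1CC"), "invalid")
})

test_that("descriptor block matches known small-molecule values", {
  d <- compute_descriptors(c("c1ccccc1", "C", "CCO"))

  benz <- d[1, ]
  expect_equal(benz$hbd, 0)
  expect_equal(benz$hba, 0)
  expect_equal(benz$rotatable_bonds, 0)
  expect_equal(benz$rings, 1)
  expect_equal(benz$radicals, 0)
  expect_equal(benz$heteroatoms, 0)
  expect_equal(benz$aromatic_carbocycles, 1)
  expect_equal(benz$amide_bonds, 0)
  expect_equal(benz$tpsa, 0)

  methane <- d[2, ]
  count_cols <- c("hbd", "hba", "rotatable_bonds", "rings", "radicals",
                  "heteroatoms", "heterocycles", "lipinski_hba",
                  "lipinski_hbd", "aromatic_carbocycles",
                  "aromatic_heterocycles", "amide_bonds",
                  "aliphatic_carbocycles", "aliphatic_heterocycles")
  expect_true(all(methane[count_cols] == 0))
  expect_equal(methane$fraction_csp3, 1.0)

  ethanol <- d[3, ]
  expect_equal(ethanol$hbd, 1)
  expect_equal(ethanol$hba, 1)
  expect_equal(ethanol$lipinski_hba, 1)
  expect_equal(ethanol$lipinski_hbd, 1)
  expect_equal(ethanol$fraction_csp3, 1.0)
})

test_that("descriptor invariants hold across the synthetic pool", {
  pool <- fixture_pool(60)
  d <- compute_descriptors(pool)
  count_cols <- setdiff(names(d), c("smiles", "fraction_csp3",
                                    "labute_asa", "tpsa"))
  for (cc in count_cols) {
    expect_true(all(d[[cc]] >= 0), info = cc)
    expect_true(all(d[[cc]] == round(d[[cc]])), info = cc)
  }
  expect_true(all(d$fraction_csp3 >= 0 & d$fraction_csp3 <= 1))
  expect_true(all(d$tpsa >= 0))
  expect_true(all(d$labute_asa >= 0))
})

test_that("feature vector has the fixed 2232 layout", {
  pool <- c(fixture_smiles(), fixture_pool(40))
  X <- build_feature_vector(pool)
  expect_equal(dim(X), c(length(pool), 2232L))

  # fingerprint segments are 0/1; MACCS slot 0 always 0
  expect_true(all(X[, 1:2215] %in% c(0, 1)))
  expect_true(all(X[, 2049] == 0))

  # descriptor tail equals compute_descriptors in declared order
  d <- compute_descriptors(pool)
  expect_equal(unname(X[, 2216:2232]), unname(as.matrix(d[, -1])),
               tolerance = 1e-12)

  # determinism: same canonical SMILES, identical vector
  expect_identical(build_feature_vector("CC(=O)Nc1ccc(O)cc1"),
                   build_feature_vector("CC(=O)Nc1ccc(O)cc1"))
})

test_that("fingerprints have fixed lengths and equivalent inputs agree", {
  fp <- compute_fingerprints(c("c1ccccc1", "C1=CC=CC=C1"))
  expect_equal(ncol(fp$path_fp), 2048L)
  expect_equal(ncol(fp$maccs), 167L)
  expect_identical(fp$path_fp[1, ], fp$path_fp[2, ])
  expect_identical(fp$maccs[1, ], fp$maccs[2, ])
  # methane: no bonds -> empty path fingerprint, reserved MACCS slot 0
  fpm <- compute_fingerprints("C")
  expect_equal(sum(fpm$path_fp), 0)
  expect_equal(unname(fpm$maccs[1, 1]), 0L)
})

test_that("isomers with equal descriptors differ only in fingerprints", {
  # para- vs meta-xylene: identical composition and descriptor block
  d <- compute_descriptors(c("Cc1ccc(C)cc1", "Cc1cccc(C)c1"))
  expect_equal(unname(unlist(d[1, -1])), unname(unlist(d[2, -1])),
               tolerance = 1e-9)
  X <- build_feature_vector(c("Cc1ccc(C)cc1", "Cc1cccc(C)c1"))
  expect_false(identical(X[1, 1:2048], X[2, 1:2048]))
  expect_equal(unname(X[1, 2216:2232]), unname(X[2, 2216:2232]),
               tolerance = 1e-9)
})

test_that("tanimoto similarity is a proper similarity", {
  expect_equal(tanimoto_similarity("CCO", "CCO"), 1.0)
  expect_equal(tanimoto_similarity("CCO", "OCC"), 1.0)
  # empty-union convention
  expect_equal(tanimoto_similarity("C", "C"), 0)

  # symmetric, unit diagonal, in [0,1] over random fixture pairs
  pool <- fixture_pool(40)
  set.seed(123)
  for (k in 1:100) {
    ab <- sample(pool, 2)
    s_ab <- tanimoto_similarity(ab[1], ab[2])
    expect_equal(s_ab, tanimoto_similarity(ab[2], ab[1]))
    expect_gte(s_ab, 0); expect_lte(s_ab, 1)
  }
  expect_true(all(vapply(pool[1:10], function(s)
    tanimoto_similarity(s, s), numeric(1)) == 1))

  # formula check on synthetic bit sets: |A^B| = 1, |AuB| = 2 -> 0.5
  expect_equal(dockgen:::tanimoto_bits(7L, c(7L, 9L)), 0.5)
  expect_equal(dockgen:::tanimoto_bits(c(1L, 2L), c(3L, 4L)), 0)
  expect_equal(dockgen:::tanimoto_bits(integer(0), integer(0)), 0)
})

test_that("descriptor block agrees with an independent recomputation", {
  # brute-force recount of graph-derived descriptors straight from the
  # molecular graph, bypassing property_table
  pool <- c("CC(=O)Nc1ccc(O)cc1", "c1ccc2c(c1)ncc(n2)N", "C1CCNCC1",
            "CC(=O)Oc1ccccc1C(=O)O", "O=C(Nc1ccccc1)Nc1ccncc1")
  d <- compute_descriptors(pool)
  for (i in seq_along(pool)) {
    g <- dockgen:::mol_graphs(canonicalize_smiles(pool[i]))[[1]]
    el <- g$atoms$element
    expect_equal(d$heteroatoms[i], sum(!el %in% c("C", "H")), info = pool[i])
    expect_equal(d$lipinski_hba[i], sum(el %in% c("N", "O")), info = pool[i])
    expect_equal(d$lipinski_hbd[i],
                 sum(g$hydrogens[el %in% c("N", "O")]), info = pool[i])
    expect_equal(d$rings[i],
                 nrow(g$bonds) - nrow(g$atoms) + g$n_components,
                 info = pool[i])
    is_c <- el == "C"
    sp3 <- is_c & !g$atoms$aromatic & g$bondsum == g$degree
    expect_equal(d$fraction_csp3[i], sum(sp3) / sum(is_c), info = pool[i])
  }
})

test_that("lipinski profile reports the seven properties", {
  p <- lipinski_profile(c("CCO", "c1ccccc1", "C"))
  expect_named(p, c("smiles", "mw", "logp", "hbd", "hba", "rotatable",
                    "aromatic_rings", "tpsa"))
  expect_equal(p$mw[1], 46.07, tolerance = 1e-3)
  expect_equal(p$hbd[1], 1)
  expect_equal(p$aromatic_rings[2], 1)
  expect_equal(p$tpsa[2], 0)
  expect_equal(p$rotatable[3], 0)
  expect_true(all(p$mw > 0))
})
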