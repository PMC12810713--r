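test_that("synthetic-accessibility scores separate simple from exotic", {
  expect_lt(sa_score("CCO"), 4)
  expect_lt(sa_score("CC[n+]1ccn(C)c1"), 4)
  expect_lt(sa_score("[O-]S(=O)(=O)C(F)(F)F"), 4)
  cage <- "C1C2CC3CC1CC(C2)(C3)C45CC6CC(C4)CC(C6)C5"
  expect_gt(sa_score(cage), 4)
  spiro_macro <- "C1CCCCCCCC12CCCCCCCC23CCCCCCCC34CCCCCCCC45CCCCCCCC5"
  expect_gt(sa_score(spiro_macro), 4)
  expect_identical(sa_score(c("CCO", "OCC")), rep(sa_score("CCO"), 2))
  expect_true(all(sa_score(c("C", "[Cl-]", cage)) >= 1 &
                    sa_score(c("C", "[Cl-]", cage)) <= 10))
})

test_that("SA ordering tracks the published fragment-based scorer", {
  ## reference values computed once with the standard public implementation
  ## of the fragment-contribution SA score and frozen here
  ref <- c(
    "CCO" = 1.98, "CCCC[n+]1ccn(C)c1" = 3.23, "CC(=O)[O-]" = 3.07,
    "[O-]S(=O)(=O)C(F)(F)F" = 3.08, "CCCCCC" = 1.21,
    "C1CC2(CC1)CC1(CCC1)CC1(CCCC1)C2" = 3.52,
    "C1CCCCCCCCCCCCC1" = 1.00,
    "C1C2CC3CC1CC(C2)(C3)C45CC6CC(C4)CC(C6)C5" = 4.09,
    "OCC(O)C(O)C(O)CO" = 3.25, "CC[N+](C)(C)CC" = 3.12,
    "[B-](F)(F)(F)F" = 3.78,
    "[N-](S(=O)(=O)C(F)(F)F)S(=O)(=O)C(F)(F)F" = 3.78,
    "C1CCCCCCCC12CCCCCCCC23CCCCCCCC34CCCCCCCC45CCCCCCCC5" = 4.36,
    "[CH2-]CC" = 3.23, "CC[O-]" = 3.79,
    "CCCCCCCCCCCCCCCCCC[n+]1ccn(C)c1" = 2.55
  )
  mine <- sa_score(names(ref))
  expect_gt(cor(mine, unname(ref), method = "spearman"), 0.55)
})

test_that("charge-sign check enforces the declared kind", {
  expect_true(charge_sign_ok("[NH4+]", "cation"))
  expect_false(charge_sign_ok("CCO", "cation"))
  expect_false(charge_sign_ok("[Cl-]", "cation"))
  expect_true(charge_sign_ok("[Cl-]", "anion"))
  expect_false(charge_sign_ok("[NH4+]", "anion"))
})

test_that("unstable-substructure patterns hit the named motifs only", {
  hits <- matches_unstable_group(c(
    "[CH2-]CC",            # bare carbanion
    "CC(=O)[O-]",          # carboxylate: resonance-stabilized, clean
    "CC[O-]",              # unstabilized alkoxide
    "CC(=O)[N+](C)(C)C",   # quaternary amide
    "[O-]S(=O)(=O)C(F)(F)F",  # clean anion
    "CC(=O)C[C-]C(=O)C"    # stabilized carbanion (alpha to carbonyl)
  ))
  expect_true("carbanion" %in% hits[[1]])
  expect_identical(hits[[2]], character(0))
  expect_true("alkoxide" %in% hits[[3]])
  expect_true("quaternary_amide" %in% hits[[4]])
  expect_identical(hits[[5]], character(0))
  expect_false("carbanion" %in% hits[[6]])
})

test_that("post-filter attributes planted violations and keeps sound ions", {
  scorer <- small_scorer()
  planted <- c(
    "CC[n+]1ccn(C)c1",          # kept: canonical IL cation
    "CCCC[n+]1ccn(C)c1",        # kept
    "C[N+](C)(C)C",             # kept
    "CCCC[N+]1(C)CCCC1",        # kept
    "not_a_smiles",             # parse
    "C1C2CC3CC1CC(C2)(C3)C45CC6CC(C4)[C+](C6)C5",  # sascore (cage cation)
    "[CH3]",                    # unpaired electrons
    "[Cl-]",                    # wrong charge sign for a cation
    "OCC(O)C(O)C(O)C[N+](C)(C)C",  # decoy-like: ion score below 0.5
    "CCCCCC(=O)[N+](C)(C)C"     # unstable group (quaternary amide)
  )
  res <- apply_post_filter(planted, "cation", scorer)
  expect_equal(nrow(res$kept), 4L)
  counts <- res$report$counts
  for (r in c("parse", "sascore", "unpaired_electrons", "charge_sign",
              "ion_score", "unstable_group")) {
    expect_equal(unname(counts[[r]]), 1L, info = r)
  }
  expect_identical(
    res$report$examples$rule[res$report$examples$smiles == "[CH3]"],
    "unpaired_electrons")
  ## idempotence and conservation
  again <- apply_post_filter(res$kept$smiles, "cation", scorer)
  expect_identical(again$kept$smiles, res$kept$smiles)
  expect_equal(nrow(res$kept) + sum(counts), length(planted))
})

test_that("post-filter decisions are invariant to SMILES spelling", {
  scorer <- small_scorer()
  a <- apply_post_filter("CC[n+]1ccn(C)c1", "cation", scorer)
  b <- apply_post_filter("C[n]1cc[n+](CC)c1", "cation", scorer)
  expect_identical(a$kept$smiles, b$kept$smiles)
  expect_equal(a$kept$score, b$kept$score)
})

test_that("scorer/kind mismatch is rejected", {
  expect_error(apply_post_filter("[Cl-]", "anion", small_scorer()),
               "does not match")
})
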