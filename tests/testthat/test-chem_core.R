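test_that("canonicalization is idempotent and dialect-invariant", {
  corpus <- c(make_il_like_corpus(25, 3, "cation")$smiles,
              make_il_like_corpus(25, 3, "anion")$smiles)
  can <- canonical_smiles(corpus)
  expect_false(anyNA(can))
  expect_identical(canonical_smiles(can), can)

  dialects <- list(
    c("OCC", "CCO"),
    c("C1=CC=CC=C1", "c1ccccc1"),
    c("C(C)(C)C", "CC(C)C"),
    c("[NH4+]", "[H][N+]([H])([H])[H]"),
    c("CC[n+]1ccn(C)c1", "C[n]1cc[n+](CC)c1"),
    c("[O-]C(=O)C", "CC([O-])=O")
  )
  for (d in dialects) {
    expect_identical(canonical_smiles(d[1]), canonical_smiles(d[2]),
                     info = paste(d, collapse = " vs "))
  }
})

test_that("parse failures are typed outcomes, never batch aborts", {
  res <- parse_smiles(c("CCO", "not_a_smiles", "C1CC", "", "CC(C)C"))
  expect_identical(res$ok, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_identical(res$canonical[1], "CCO")
  expect_true(all(is.na(res$canonical[!res$ok])))
})

test_that("net formal charge equals hand-counted charges", {
  ions <- c("[NH4+]" = 1L, "[O-]S(=O)(=O)[O-]" = -2L, "CCO" = 0L,
            "CC[n+]1ccn(C)c1" = 1L, "[B-](F)(F)(F)F" = -1L,
            "[Fe+2]" = 2L, "[O-]C(=O)CC(=O)[O-]" = -2L,
            "C[N+](C)(C)CC[N+](C)(C)C" = 2L, "[Cl-]" = -1L,
            "O=[N+]([O-])[O-]" = -1L)
  expect_identical(net_formal_charge(names(ions)), unname(ions))
})

test_that("element whitelist check honours the printed list and sulfur flag", {
  expect_true(contains_only_elements("[B-](F)(F)(F)F"))
  expect_false(contains_only_elements("[SeH2]"))
  expect_false(contains_only_elements("CS(C)C"))  # S absent from default list
  expect_true(contains_only_elements("CS(C)C", il_elements(include_sulfur = TRUE)))
  expect_true(contains_only_elements("CCO"))
})

test_that("descriptor vectors are aligned, finite and spelling-invariant", {
  d <- compute_descriptors(c("CCO", "OCC", "CC[n+]1ccn(C)c1"))
  expect_identical(setdiff(names(d), "smiles"), as.vector(il_descriptor_set()))
  expect_true(all(is.finite(as.matrix(d[, -1L]))))
  expect_equal(d$mw[1], 46.07, tolerance = 0.01)
  expect_equal(as.matrix(d[1, -1L]), as.matrix(d[2, -1L]),
               ignore_attr = TRUE)
  d2 <- compute_descriptors(c("CCO", "OCC", "CC[n+]1ccn(C)c1"))
  expect_identical(as.matrix(d[, -1L]), as.matrix(d2[, -1L]))
  expect_error(compute_descriptors("CCO", descriptors = "no_such"),
               "Unknown descriptors")
})

test_that("ECFP fingerprints distinguish structures and unify spellings", {
  fp <- compute_ecfp(c("CCO", "OCC", "CCCC", "c1ccccc1"))
  expect_equal(tanimoto(fp[1, ], fp[2, ]), 1)
  expect_lt(tanimoto(fp[3, ], fp[4, ]), 1)
  expect_true(all(rowSums(fp) >= 1))
  expect_error(compute_ecfp("not_a_smiles"), "Unparseable")
  expect_error(compute_ecfp("CCO", radius = 0L))
  expect_error(compute_ecfp("CCO", nbits = 1000L))  # not a power of two
})

test_that("in-package ECFP similarity agrees with the toolkit fingerprinter", {
  smis <- c("CCO", "CCCO", "CCCCO", "c1ccccc1", "Cc1ccccc1",
            "CC[n+]1ccn(C)c1", "CCCC[n+]1ccn(C)c1", "CC(=O)[O-]")
  fp_mine <- compute_ecfp(smis, nbits = 4096)
  fp_ob <- ChemmineOB::fingerprint_OB(
    ChemmineOB::forEachMol("SMILES", paste(canonical_smiles(smis),
                                           collapse = "\n"), identity),
    "ECFP4")
  pairs <- utils::combn(length(smis), 2L)
  sim_mine <- apply(pairs, 2L, function(ij) {
    tanimoto(fp_mine[ij[1], ], fp_mine[ij[2], ])
  })
  sim_ob <- apply(pairs, 2L, function(ij) {
    tanimoto(fp_ob[ij[1], ] > 0, fp_ob[ij[2], ] > 0)
  })
  ## two independent implementations (different hashes, same algorithm
  ## family) must order pairwise similarities consistently
  expect_gt(cor(sim_mine, sim_ob, method = "spearman"), 0.8)
})
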