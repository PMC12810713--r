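test_that("generation metrics follow their definitions", {
  m <- generation_metrics(c("CCO", "OCC", "xx"), character(0))
  expect_equal(m$validity, 2 / 3)
  expect_equal(m$uniqueness, 1 / 2)   # CCO and OCC are one structure
  expect_equal(m$novelty, 1.0)
  expect_equal(m$n_sampled, 3L)

  all_known <- generation_metrics(c("CCO", "CCC"), c("OCC", "CCC"))
  expect_equal(all_known$novelty, 0)

  none <- generation_metrics(c("xx", "yy"), "CCO")
  expect_equal(none$validity, 0)
  expect_true(is.na(none$uniqueness) && is.na(none$novelty))
})

test_that("ion combination is the exact deduplicated Cartesian product", {
  p <- combine_ions(c("C[N+](C)(C)C", "CC[n+]1ccn(C)c1"),
                    c("[Cl-]", "[Br-]", "[I-]"))
  expect_equal(nrow(p), 6L)
  expect_false(any(duplicated(paste(p$cation_smiles, p$anion_smiles))))
  ## cation-major deterministic order
  expect_identical(p$cation_smiles, rep(unique(p$cation_smiles), each = 3L))

  expect_warning(
    p2 <- combine_ions(c("C[N+](C)(C)C", "C[N+](C)(C)C"), "[Cl-]"),
    "Duplicate")
  expect_equal(nrow(p2), 1L)
  expect_error(combine_ions(character(0), "[Cl-]"), "Empty")
})

test_that("combination cardinality law holds across random sizes", {
  cat_pool <- make_il_like_corpus(30, 3, "cation")$smiles
  an_pool <- make_il_like_corpus(30, 3, "anion")$smiles
  withr::with_seed(8, {
    for (i in 1:5) {
      nc <- sample(1:30, 1); na <- sample(1:30, 1)
      p <- combine_ions(cat_pool[seq_len(nc)], an_pool[seq_len(na)])
      expect_equal(nrow(p), nc * na)
    }
  })
})

test_that("ranking selects the lowest predicted melting points, sorted", {
  m <- small_mpt()
  pairs <- combine_ions(make_il_like_corpus(8, 4, "cation")$smiles,
                        make_il_like_corpus(8, 4, "anion")$smiles)
  sel <- rank_and_select(pairs, m, top_n = 20L)
  expect_equal(nrow(sel), 20L)
  expect_identical(sel$rank, 1:20)
  expect_true(!is.unsorted(sel$pred_mpt_K))

  all_pred <- predict_mpt(m, pairs$cation_smiles, pairs$anion_smiles)
  expect_equal(sel$pred_mpt_K[1], min(all_pred))   # planted minimum first
  expect_true(all(paste(sel$cation_smiles, sel$anion_smiles) %in%
                    paste(pairs$cation_smiles, pairs$anion_smiles)))

  full <- rank_and_select(pairs, m, top_n = nrow(pairs))
  expect_setequal(paste(full$cation_smiles, full$anion_smiles),
                  paste(pairs$cation_smiles, pairs$anion_smiles))
  expect_error(rank_and_select(pairs, m, top_n = nrow(pairs) + 1L))
})

test_that("chemical-space projection co-locates duplicates and is seeded", {
  smis <- c(make_il_like_corpus(12, 6, "cation")$smiles,
            "CC[n+]1ccn(C)c1", "CC[n+]1ccn(C)c1")
  coords <- project_chemical_space(smis, seed = 4)
  expect_equal(nrow(coords), length(unique(c(smis))) +
                 sum(duplicated(smis)))
  dup_idx <- which(coords$smiles == "CC[n+]1ccn(C)c1")
  expect_gte(length(dup_idx), 2L)
  span <- max(dist(cbind(coords$x, coords$y)))
  d_dup <- sqrt(diff(coords$x[dup_idx[1:2]])^2 +
                  diff(coords$y[dup_idx[1:2]])^2)
  expect_lt(d_dup, 0.01 * span)

  coords2 <- project_chemical_space(smis, seed = 4)
  expect_identical(coords, coords2)

  withdrop <- project_chemical_space(c(smis, "bad_smiles"), seed = 4)
  expect_equal(attr(withdrop, "n_dropped"), 1L)
  expect_error(project_chemical_space(c("CCO", "CCC"), seed = 1))  # < 10

  nm <- project_chemical_space(smis, seed = 4, method = "nmds")
  expect_identical(nm, project_chemical_space(smis, seed = 4,
                                              method = "nmds"))
})
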