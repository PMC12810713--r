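test_that("general-ion filter attributes every planted violation to its rule", {
  fx <- curation_fixture()
  res <- filter_general_ions(fx$ions)

  expect_equal(nrow(res$kept), fx$n_clean)
  expect_equal(res$report$n_input, nrow(fx$ions))
  got <- res$report$examples
  expect_equal(nrow(got), nrow(fx$plants))
  expect_identical(got$rule[match(fx$plants$smiles, got$smiles)],
                   fx$plants$rule)
  counts <- table(fx$plants$rule)
  for (r in names(counts)) {
    expect_equal(unname(res$report$counts[[r]]), unname(counts[[r]]), info = r)
  }
  ## conservation: kept + rejected == input
  expect_equal(nrow(res$kept) + sum(res$report$counts), res$report$n_input)
})

test_that("general-ion filter is order-stable and idempotent", {
  fx <- curation_fixture()
  res <- filter_general_ions(fx$ions)
  perm <- withr::with_seed(1, sample.int(nrow(fx$ions)))
  res_perm <- filter_general_ions(fx$ions[perm, ])
  expect_setequal(res_perm$kept$smiles, res$kept$smiles)
  expect_identical(sort(res_perm$report$counts), sort(res$report$counts))

  again <- filter_general_ions(res$kept)
  expect_identical(again$kept$smiles, res$kept$smiles)
  expect_true(all(again$report$counts == 0L))
})

test_that("simple ions pass every curation bound", {
  res <- filter_general_ions(
    tibble::tibble(smiles = c("[NH4+]", "CC[n+]1ccn(C)c1"), kind = "cation"))
  expect_equal(nrow(res$kept), 2L)
  expect_true(all(c("net_charge", "mw") %in% names(res$kept)))
})

test_that("IL-record filter splits pairs and rejects bad compositions", {
  res <- filter_il_records(c(
    "[B-](F)(F)(F)F.CC[n+]1ccn(C)c1",
    "CC[n+]1ccn(C)c1.[B-](F)(F)(F)F",   # same pair, other order
    "C[N+](C)(C)C.[Cl-].[Br-]",          # three ions
    "CC[n+]1ccn(C)c1.[Cl-].O",           # neutral co-component (hydrate)
    "C[N+](C)(C)C.C[N+](C)(C)C",         # two cations, no anion
    "not_a_smiles",
    "[SeH-].C[N+](C)(C)C"                # uncommon element
  ))
  expect_equal(nrow(res$kept), 1L)
  expect_identical(res$kept$cation_smiles, canonical_smiles("CC[n+]1ccn(C)c1"))
  expect_identical(res$kept$anion_smiles, canonical_smiles("[B-](F)(F)(F)F"))
  expect_equal(unname(res$report$counts[["component_count"]]), 2L)
  expect_equal(unname(res$report$counts[["charge_composition"]]), 1L)
  expect_equal(unname(res$report$counts[["parse"]]), 1L)
  expect_equal(unname(res$report$counts[["elements"]]), 1L)
})

test_that("melting-point deduplication follows the 10 K rule", {
  rec <- tibble::tibble(
    cation_smiles = c("CC[n+]1ccn(C)c1", "CC[n+]1ccn(C)c1",
                      "C[N+](C)(C)C", "C[N+](C)(C)C",
                      "CCCC[n+]1ccn(C)c1"),
    anion_smiles = c("[Cl-]", "[Cl-]", "[Br-]", "[Br-]", "[I-]"),
    mpt_K = c(300, 305, 300, 315, 412)
  )
  out <- deduplicate_mpt(rec)
  expect_equal(nrow(out), 2L)
  merged <- out[out$anion_smiles == "[Cl-]", ]
  expect_equal(merged$mpt_K, 302.5)
  expect_identical(merged$source, "merged")
  expect_equal(out$mpt_K[out$anion_smiles == "[I-]"], 412)
  ## the >10 K group is gone entirely
  expect_false("[Br-]" %in% out$anion_smiles)
})

test_that("deduplicated records have unique pair keys (property)", {
  pool_c <- make_il_like_corpus(15, 2, "cation")$smiles
  pool_a <- make_il_like_corpus(10, 2, "anion")$smiles
  rec <- withr::with_seed(5, tibble::tibble(
    cation_smiles = sample(pool_c, 120, replace = TRUE),
    anion_smiles = sample(pool_a, 120, replace = TRUE),
    mpt_K = runif(120, 250, 500)
  ))
  out <- deduplicate_mpt(rec, tolerance = 50)
  expect_false(any(duplicated(paste(out$cation_smiles, out$anion_smiles))))
  ## tolerance 0 keeps only groups with identical values
  out0 <- deduplicate_mpt(rec, tolerance = 0)
  expect_false(any(duplicated(paste(out0$cation_smiles, out0$anion_smiles))))
})
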