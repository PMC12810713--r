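test_that("pair featurization is order-invariant and complete", {
  f1 <- featurize_pairs("CC[n+]1ccn(C)c1", "[O-]S(=O)(=O)C(F)(F)F")
  f2 <- featurize_pairs("[O-]S(=O)(=O)C(F)(F)F", "CC[n+]1ccn(C)c1")
  expect_identical(f1, f2)
  expect_identical(f1$cation_smiles, canonical_smiles("CC[n+]1ccn(C)c1"))
  expect_equal(ncol(f1) - 3L, 2L * length(il_descriptor_set()))
  expect_error(featurize_pairs("xxx", "[Cl-]"), "Unparseable")
})

test_that("combined-mode featurization is additive in mass", {
  cat_s <- "CC[n+]1ccn(C)c1"
  an_s <- "[O-]S(=O)(=O)C(F)(F)F"
  pair <- featurize_pairs(cat_s, an_s, mode = "combined")
  ions <- compute_descriptors(c(cat_s, an_s))
  expect_equal(pair$mw, sum(ions$mw), tolerance = 0.01)
  expect_equal(pair$hbd, sum(ions$hbd))
  expect_equal(pair$n_C, sum(ions$n_C))
  expect_equal(ncol(pair) - 3L, length(il_descriptor_set()))
  ## combined mode is order-invariant too
  pair2 <- featurize_pairs(an_s, cat_s, mode = "combined")
  expect_identical(pair, pair2)
})

test_that("regression metrics match closed forms", {
  perfect <- evaluate_mpt(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$r2, 1)

  truths <- c(10, 20, 30, 40)
  at_mean <- evaluate_mpt(rep(mean(truths), 4), truths)
  expect_equal(at_mean$r2, 0)

  hand <- evaluate_mpt(c(0, 0), c(0, 10))
  expect_equal(hand$rmse, sqrt(50), tolerance = 1e-6)  # 7.0711
  expect_equal(hand$mae, 5)

  expect_error(evaluate_mpt(c(1, 2), c(5, 5)), "constant")

  ## rmse >= mae and r2 <= 1 for arbitrary data (property)
  withr::with_seed(3, {
    for (i in 1:20) {
      p <- rnorm(30); t <- rnorm(30)
      m <- evaluate_mpt(p, t)
      expect_gte(m$rmse, m$mae)
      expect_lte(m$r2, 1)
    }
  })
})

test_that("forest interpolates duplicated zero-noise records", {
  base <- make_synthetic_mpt_dataset(60, 21, noise_sigma = 0)[1:10, ]
  dup <- base[rep(1:10, each = 6), ]
  m <- train_mpt(dup, seed = 2, num_trees = 200)
  pred <- predict_mpt(m, base$cation_smiles, base$anion_smiles)
  expect_lt(sqrt(mean((pred - base$mpt_K)^2)), 10)
})

test_that("training is seed-stable and prediction batched/consistent", {
  m <- small_mpt()
  m2 <- train_mpt(make_synthetic_mpt_dataset(150, 7), seed = 7,
                  num_trees = 200)
  expect_identical(m$split, m2$split)
  expect_identical(m$metrics, m2$metrics)

  c2 <- c("CC[n+]1ccn(C)c1", "CCCCCCCC[n+]1ccn(C)c1")
  a2 <- c("[Cl-]", "[O-]S(=O)(=O)C(F)(F)F")
  batch <- predict_mpt(m, c2, a2)
  expect_equal(batch, c(predict_mpt(m, c2[1], a2[1]),
                        predict_mpt(m, c2[2], a2[2])))
  expect_true(all(batch > 0))
})

test_that("model ranks planted low-melting pairs above high-melting ones", {
  m <- small_mpt()
  d <- make_synthetic_mpt_dataset(200, 31)
  pred <- predict_mpt(m, d$cation_smiles, d$anion_smiles)
  expect_gte(cor(pred, d$mpt_true, method = "spearman"), 0.7)
})

test_that("unavailable backends fail with guidance", {
  d <- make_synthetic_mpt_dataset(60, 2)
  expect_error(train_mpt(d, backend = "tabular_foundation"),
               "pretrained")
  expect_error(train_mpt(d[1:10, ]))  # too few records
})

test_that("xgboost backend trains and predicts", {
  skip_if_not_installed("xgboost")
  d <- make_synthetic_mpt_dataset(150, 7)
  m <- train_mpt(d, backend = "xgboost", seed = 7, num_trees = 150)
  expect_gt(m$metrics$r2, 0.5)
  p <- predict_mpt(m, "CC[n+]1ccn(C)c1", "[Cl-]")
  expect_true(is.finite(p) && p > 0)
})
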