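test_that("label smoothing matches its closed form and symmetry", {
  expect_equal(smooth_labels(1, alpha = 0.2), 0.9)
  expect_equal(smooth_labels(0, alpha = 0.2), 0.1)
  expect_equal(smooth_labels(1, alpha = 0), 1.0)
  for (a in c(0, 0.1, 0.2, 0.5, 0.9)) {
    expect_equal(smooth_labels(1, a) + smooth_labels(0, a), 1)  # K = 2
  }
  ## affine and order preserving
  expect_true(smooth_labels(1, 0.3) > smooth_labels(0, 0.3))
  expect_error(smooth_labels(0.5))
  expect_error(smooth_labels(1, alpha = 1))
})

test_that("scorer dataset is balanced, split 80:20 and seed-stable", {
  ds <- small_ion_ds()
  expect_equal(sum(ds$label == 1), sum(ds$label == 0))
  tab <- table(ds$label, ds$split)
  expect_equal(unname(tab[, "test"] / rowSums(tab)), c(0.2, 0.2),
               tolerance = 0.02)
  il <- make_il_like_corpus(120, 7, "cation")
  de <- make_decoy_corpus(120, 7, "cation")
  ds2 <- build_scorer_dataset(il, de, seed = 7)
  expect_identical(ds$smiles, ds2$smiles)
  expect_identical(ds$split, ds2$split)
  expect_error(build_scorer_dataset(il, de[1:50, ], seed = 7),
               "at least as many")
})

test_that("L1 selection recovers planted informative features", {
  ds <- synthetic_ds()
  top <- select_features(ds, k = 3, seed = 1)
  expect_setequal(as.vector(top), c("f1", "f2", "f3"))

  all_feats <- select_features(ds, k = 8, seed = 1)
  expect_setequal(as.vector(all_feats), attr(ds, "feature_cols"))

  ## perfectly correlated informative pair: at least one survives
  ds2 <- synthetic_ds(informative = c("f1", "f2"), n_noise = 3)
  ds2$f2 <- ds2$f1
  attr(ds2, "feature_cols") <- c("f1", "f2", paste0("noise", 1:3))
  top2 <- select_features(ds2, k = 2, seed = 1)
  expect_true(any(c("f1", "f2") %in% top2))

  ## constant features are excluded and logged
  ds3 <- synthetic_ds()
  ds3$noise1 <- 1
  sel <- select_features(ds3, k = 3, seed = 1)
  expect_identical(attr(sel, "dropped_constant"), "noise1")
})

test_that("alpha = 0 training matches the standard hard-label solver", {
  ds <- synthetic_ds(shift = 1.2, seed = 4)   # overlapping classes
  feats <- c("f1", "f2", "f3")
  m <- train_scorer(ds, feats, alpha = 0)

  train <- ds[ds$split == "train", ]
  xz <- scale(as.matrix(train[, feats]))
  oracle <- stats::glm(train$label ~ xz, family = stats::binomial())
  expect_equal(unname(m$intercept), unname(coef(oracle)[1]),
               tolerance = 1e-4)
  expect_equal(unname(m$weights), unname(coef(oracle)[-1]),
               tolerance = 1e-4)
})

test_that("label smoothing bounds predicted probabilities away from 1", {
  ds <- synthetic_ds(shift = 8, seed = 9)   # (near-)separable
  feats <- c("f1", "f2", "f3")
  m_smooth <- train_scorer(ds, feats, alpha = 0.2)
  train <- ds[ds$split == "train", ]
  xz <- sweep(sweep(as.matrix(train[, feats]), 2,
                    m_smooth$standardization$mean),
              2, m_smooth$standardization$sd, "/")
  p_smooth <- stats::plogis(drop(xz %*% m_smooth$weights) + m_smooth$intercept)
  expect_lt(max(p_smooth), 0.99)
  expect_gt(min(p_smooth), 0.01)
})

test_that("scores are spelling-invariant and reproducible; threshold is inclusive", {
  m <- small_scorer()
  s <- score_ions(m, c("CCCC[n+]1ccn(C)c1", "C(CCC)[n+]1ccn(C)c1"))
  expect_equal(s$score[1], s$score[2])
  expect_true(all(s$score > 0 & s$score < 1))
  s2 <- score_ions(m, "CCCC[n+]1ccn(C)c1")
  expect_identical(s$score[1], s2$score[1])

  expect_identical(discretize_score(c(0.7, 0.3, 0.5)), c(1L, 0L, 1L))
  bad <- score_ions(m, c("CCCC[n+]1ccn(C)c1", "xxx"))
  expect_true(is.na(bad$score[2]))
  expect_identical(attr(bad, "failures"), "xxx")
})

test_that("scorer evaluation reports accuracy, recall and ROC-AUC sanely", {
  ds <- small_ion_ds()
  m <- small_scorer()
  ev <- evaluate_scorer(m, ds, "test")
  expect_true(ev$accuracy > 0.8 && ev$accuracy <= 1)
  expect_true(ev$recall > 0.8 && ev$recall <= 1)
  expect_true(ev$roc_auc > 0.9 && ev$roc_auc <= 1)

  ## label-free scores hover at chance AUC
  ds_perm <- ds
  ds_perm$label <- withr::with_seed(13, sample(ds$label))
  m_perm <- train_scorer(ds_perm, select_features(ds_perm, k = 10, seed = 1),
                         alpha = 0.2, ion_kind = "cation")
  ev_perm <- evaluate_scorer(m_perm, ds_perm, "test")
  expect_gt(ev_perm$roc_auc, 0.2)
  expect_lt(ev_perm$roc_auc, 0.8)

  single <- ds[ds$label == 1, ]
  attr(single, "feature_cols") <- attr(ds, "feature_cols")
  expect_error(evaluate_scorer(m, single, "test"), "single-class")
})

test_that("scorer JSON round trip preserves scores; tidy/glance work", {
  m <- small_scorer()
  path <- withr::local_tempfile(fileext = ".json")
  write_scorer(m, path)
  m2 <- read_scorer(path)
  s1 <- score_ions(m, "CCCCCC[n+]1ccn(C)c1")$score
  s2 <- score_ions(m2, "CCCCCC[n+]1ccn(C)c1")$score
  expect_equal(s1, s2, tolerance = 1e-12)

  td <- tidy(m)
  expect_identical(td$term[1], "(Intercept)")
  expect_equal(nrow(td), length(m$selected_features) + 1L)
  expect_identical(glance(m)$ion_kind, "cation")
})
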