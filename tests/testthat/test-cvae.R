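test_that("vocabulary enumerates characters with fixed specials", {
  v <- build_vocabulary(c("CC", "CO"))
  expect_length(v$id_to_token, 5L)   # C, O + 3 specials
  expect_identical(unname(v$specials), 1:3)
  v2 <- build_vocabulary(c("CO", "CC"))
  expect_identical(v$token_to_id, v2$token_to_id)
  v3 <- build_vocabulary("[nH+]")
  expect_true(all(c("[", "n", "H", "+", "]") %in% names(v3$token_to_id)))
})

test_that("tokenization round-trips and errors are informative", {
  corpus <- make_il_like_corpus(40, 5, "cation")$smiles
  v <- build_vocabulary(corpus)
  seqs <- tokenize_smiles(corpus, v)
  back <- vapply(seqs, detokenize_smiles, character(1), vocab = v)
  expect_identical(back, corpus)
  expect_true(all(vapply(seqs, function(s) {
    s[1] == v$specials[["BOS"]] && s[length(s)] == v$specials[["EOS"]]
  }, logical(1))))

  expect_identical(tokenize_smiles("", v)[[1]],
                   c(v$specials[["BOS"]], v$specials[["EOS"]]))
  expect_error(tokenize_smiles("CC%CC", v), "Out-of-vocabulary")
  expect_error(tokenize_smiles(strrep("C", 200), v, max_len = 32),
               "longer than max_len")
})

test_that("cyclic KL annealing ramps, holds and resets", {
  sch <- anneal_schedule(n_cycles = 4, ramp_fraction = 0.5, beta_max = 1)
  total <- 400  # cycle length 100
  expect_equal(kl_anneal_weight(0, total, sch), 0)
  expect_equal(kl_anneal_weight(25, total, sch), 0.5)   # quarter cycle
  expect_equal(kl_anneal_weight(50, total, sch), 1)
  expect_equal(kl_anneal_weight(80, total, sch), 1)     # hold phase
  expect_equal(kl_anneal_weight(100, total, sch), 0)    # second cycle start
  steps <- 0:399
  w <- kl_anneal_weight(steps, total, sch)
  expect_true(all(w >= 0 & w <= 1))
  expect_equal(w[1:100], w[101:200])  # periodicity
})

test_that("Gaussian KL matches closed form and Monte-Carlo estimate", {
  expect_equal(ilgen:::gaussian_kl(1, 0), 0.5)   # mu=1, sigma=1, d=1
  expect_equal(ilgen:::gaussian_kl(0, 0), 0)
  withr::with_seed(2, {
    mu <- rnorm(4, 0, 0.8)
    logvar <- rnorm(4, 0, 0.4)
    closed <- ilgen:::gaussian_kl(mu, logvar)
    ## MC estimate of E_q[log q - log p]
    n <- 4e5
    z <- matrix(rnorm(n * 4), n, 4)
    z <- sweep(sweep(z, 2, exp(0.5 * logvar), "*"), 2, mu, "+")
    logq <- sapply(1:4, function(j) {
      dnorm(z[, j], mu[j], exp(0.5 * logvar[j]), log = TRUE)
    })
    logp <- dnorm(z, log = TRUE)
    mc <- mean(rowSums(logq - logp))
    expect_equal(mc, closed, tolerance = 0.02)
  })
})

test_that("analytic gradients match finite differences", {
  cfg <- cvae_config(embed_dim = 5, hidden_dim = 6, n_gru_layers = 2,
                     latent_dim = 4, batch_size = 3, epochs = 1,
                     max_len = 16, seed = 9)
  smis <- c("CCO", "CC(N)=O", "c1ccccc1")
  vocab <- build_vocabulary(smis)
  batch <- list(ids = ilgen:::pad_batch(tokenize_smiles(smis, vocab, 16)),
                cond = c(1, 0, 1))
  params <- ilgen:::with_seed(5,
    ilgen:::.cvae_init_params(length(vocab$id_to_token), cfg))
  eps <- ilgen:::with_seed(6, matrix(rnorm(3 * 4), 3, 4))
  out <- ilgen:::.cvae_batch(params, cfg, batch, beta = 0.7, eps = eps)

  fd <- function(k, i, h = 1e-5) {
    p1 <- params; p1[[k]][i] <- p1[[k]][i] + h
    p2 <- params; p2[[k]][i] <- p2[[k]][i] - h
    l1 <- ilgen:::.cvae_batch(p1, cfg, batch, 0.7, eps = eps,
                              want_grads = FALSE)$total
    l2 <- ilgen:::.cvae_batch(p2, cfg, batch, 0.7, eps = eps,
                              want_grads = FALSE)$total
    (l1 - l2) / (2 * h)
  }
  withr::with_seed(11, {
    for (k in c("emb", "enc_Wi_1", "enc_Wh_2", "w_mu", "w_lv", "dec0_W_1",
                "dec_Wi_1", "dec_Wh_2", "w_out", "b_out")) {
      for (i in sample(length(params[[k]]), 3)) {
        g_an <- out$grads[[k]][i]
        g_fd <- fd(k, i)
        expect_lt(abs(g_an - g_fd) / max(1e-4, abs(g_an) + abs(g_fd)), 1e-3)
      }
    }
  })
})

test_that("loss decomposes as recon + beta * kl", {
  m <- tiny_cvae()
  dat <- tibble::tibble(smiles = m$training_smiles[1:20], condition = 1)
  l0 <- cvae_loss(m, dat, beta = 0)
  l1 <- cvae_loss(m, dat, beta = 1)
  expect_equal(l0$total, l0$recon)
  expect_equal(l1$total, l1$recon + l1$kl)
  expect_gte(l1$kl, 0)
  expect_gte(l1$recon, 0)
})

test_that("toy training reduces reconstruction loss and is seed-exact", {
  m <- tiny_cvae()
  h <- m$history
  expect_lt(h$recon[nrow(h)], h$recon[1])
  ## bitwise determinism of the full loss history under the same seed
  il <- make_il_like_corpus(75, 7, "cation")
  de <- make_decoy_corpus(75, 7, "cation")
  dat <- tibble::tibble(smiles = c(il$smiles, de$smiles),
                        condition = rep(c(1, 0), each = 75))
  m2 <- train_cvae(dat, m$config)
  expect_identical(m$history, m2$history)
  expect_identical(m$params$w_out, m2$params$w_out)
})

test_that("a single-string model memorizes: reconstruction and sampling", {
  m <- memor_cvae()
  expect_lt(tail(m$history$recon, 1), 1)
  dat <- tibble::tibble(smiles = "CC[n+]1ccn(C)c1", condition = 1)
  expect_equal(reconstruction_accuracy(m, dat), 1.0)
  s <- sample_ions(m, 50, condition = 1, seed = 2)
  expect_gt(mean(s == "CC[n+]1ccn(C)c1"), 0.5)
})

test_that("sampling is seeded, sized and condition-aware", {
  m <- tiny_cvae()
  expect_identical(sample_ions(m, 0, seed = 1), character(0))
  s1 <- sample_ions(m, 25, condition = 1, seed = 5)
  s2 <- sample_ions(m, 25, condition = 1, seed = 5)
  expect_identical(s1, s2)
  s3 <- sample_ions(m, 25, condition = 1, seed = 6)
  expect_false(identical(s1, s3))
  expect_length(s1, 25L)
})

test_that("reconstruction accuracy is bounded and near zero for an untrained model", {
  cfg <- cvae_config(embed_dim = 8, hidden_dim = 12, n_gru_layers = 1,
                     latent_dim = 4, epochs = 1, batch_size = 32,
                     lr = 1e-9, max_len = 64, seed = 21)
  corpus <- make_il_like_corpus(60, 9, "cation")$smiles
  m <- train_cvae(tibble::tibble(smiles = corpus, condition = 1), cfg)
  acc <- reconstruction_accuracy(
    m, tibble::tibble(smiles = corpus[1:40], condition = 1))
  expect_gte(acc, 0)
  expect_lt(acc, 0.2)
})
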