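## Conditional variational autoencoder over SMILES characters.
##
## Architecture (matching the generative-chemistry GRU-VAE convention):
##  * encoder: stacked GRUs; input at each step is [token embedding || c],
##    where c in {0, 1} is the condition (discretized ion score); the top
##    layer's final hidden state maps linearly to the posterior mean and
##    log-variance;
##  * latent: diagonal Gaussian, reparameterized during training, posterior
##    mean during reconstruction; prior N(0, I);
##  * decoder: [z || c] maps through a tanh linear layer to each layer's
##    initial hidden state; input at each step is [token embedding || c]
##    (teacher forcing during training); a linear head produces token logits.
##
## The loss is the conditional ELBO: per-sequence token cross-entropy plus
## beta times the closed-form Gaussian KL to the prior, with beta following
## a cyclic annealing schedule.
##
## Everything - forward, backward (full BPTT), Adam - is implemented with
## plain matrix algebra; gradients are validated against central finite
## differences in the test suite.

#' Cyclic KL annealing schedule
#'
#' @param n_cycles Number of annealing cycles over the whole run (default 4).
#' @param ramp_fraction Fraction of each cycle spent ramping linearly from 0
#'   to `beta_max`; the remainder holds at `beta_max` (default 0.5).
#' @param beta_max Maximum KL weight (default 1).
#' @return A list of class `"anneal_schedule"`.
#' @export
anneal_schedule <- function(n_cycles = 4L, ramp_fraction = 0.5,
                            beta_max = 1.0) {
  stopifnot(n_cycles >= 1L, ramp_fraction > 0, ramp_fraction <= 1,
            beta_max >= 0)
  structure(list(n_cycles = n_cycles, ramp_fraction = ramp_fraction,
                 beta_max = beta_max), class = "anneal_schedule")
}

#' KL weight at a training step
#'
#' Piecewise-linear cyclic schedule: within each cycle of length
#' `total_steps / n_cycles` the weight rises linearly from 0 to `beta_max`
#' over the first `ramp_fraction` of the cycle, then stays at `beta_max`;
#' it resets to 0 at every cycle start.
#'
#' @param step 0-based global step, `0 <= step < total_steps`.
#' @param total_steps Total optimizer steps in the run.
#' @param schedule An [anneal_schedule()].
#' @return The KL weight in `[0, beta_max]`.
#' @export
kl_anneal_weight <- function(step, total_steps, schedule = anneal_schedule()) {
  stopifnot(all(step >= 0), all(step < total_steps))
  cycle_len <- total_steps / schedule$n_cycles
  pos <- step %% cycle_len
  ramp <- schedule$ramp_fraction * cycle_len
  pmin(pos / ramp, 1) * schedule$beta_max
}

#' CVAE configuration
#'
#' Defaults are the full-scale settings used for ion generation: 292-d
#' embeddings and GRU hidden states, three GRU layers, a 128-d latent space
#' (the condition scalar is extra), Adam at learning rate 1e-4, batch size
#' 128, 100 epochs. Tests and examples use much smaller models; the
#' architecture is identical.
#'
#' @param embed_dim,hidden_dim,n_gru_layers,latent_dim Model dimensions.
#' @param lr,batch_size,epochs Optimizer settings.
#' @param max_len Maximum tokenized length (specials included); longer
#'   training strings are excluded with a logged count.
#' @param anneal An [anneal_schedule()].
#' @param grad_clip Global gradient-norm clip (stability guard).
#' @param seed Integer seed controlling initialization, shuffling, and the
#'   reparameterization noise.
#' @return A list of class `"cvae_config"`.
#' @export
cvae_config <- function(embed_dim = 292L, hidden_dim = 292L,
                        n_gru_layers = 3L, latent_dim = 128L,
                        lr = 1e-4, batch_size = 128L, epochs = 100L,
                        max_len = 128L, anneal = anneal_schedule(),
                        grad_clip = 5, seed = 1L) {
  stopifnot(embed_dim > 0L, hidden_dim > 0L, n_gru_layers > 0L,
            latent_dim > 0L, lr > 0, batch_size > 0L, epochs > 0L,
            max_len >= 3L, inherits(anneal, "anneal_schedule"))
  structure(list(embed_dim = as.integer(embed_dim),
                 hidden_dim = as.integer(hidden_dim),
                 n_gru_layers = as.integer(n_gru_layers),
                 latent_dim = as.integer(latent_dim),
                 lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), max_len = as.integer(max_len),
                 anneal = anneal, grad_clip = grad_clip,
                 seed = as.integer(seed)),
            class = "cvae_config")
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.init_mat <- function(nr, nc) {
  s <- 1 / sqrt(nr)
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

## Parameter initialization (flat named list of matrices / vectors).
.cvae_init_params <- function(vocab_size, cfg) {
  E <- cfg$embed_dim; H <- cfg$hidden_dim; Z <- cfg$latent_dim
  L <- cfg$n_gru_layers
  p <- list(emb = .init_mat(vocab_size, E))
  for (side in c("enc", "dec")) {
    for (l in seq_len(L)) {
      d_in <- if (l == 1L) E + 1L else H
      p[[paste0(side, "_Wi_", l)]] <- .init_mat(d_in, 3L * H)
      p[[paste0(side, "_Wh_", l)]] <- .init_mat(H, 3L * H)
      p[[paste0(side, "_bi_", l)]] <- numeric(3L * H)
      p[[paste0(side, "_bh_", l)]] <- numeric(3L * H)
    }
  }
  p$w_mu <- .init_mat(H, Z); p$b_mu <- numeric(Z)
  p$w_lv <- .init_mat(H, Z); p$b_lv <- numeric(Z)
  for (l in seq_len(L)) {
    p[[paste0("dec0_W_", l)]] <- .init_mat(Z + 1L, H)
    p[[paste0("dec0_b_", l)]] <- numeric(H)
  }
  p$w_out <- .init_mat(H, vocab_size); p$b_out <- numeric(vocab_size)
  p
}

## ---- GRU cell ------------------------------------------------------------

.gru_forward <- function(x, h, Wi, Wh, bi, bh) {
  H <- ncol(Wh) / 3L
  gi <- x %*% Wi
  gi <- sweep(gi, 2L, bi, "+")
  gh <- h %*% Wh
  gh <- sweep(gh, 2L, bh, "+")
  i1 <- seq_len(H); i2 <- i1 + H; i3 <- i2 + H
  r <- .sigmoid(gi[, i1, drop = FALSE] + gh[, i1, drop = FALSE])
  z <- .sigmoid(gi[, i2, drop = FALSE] + gh[, i2, drop = FALSE])
  ghn <- gh[, i3, drop = FALSE]
  n <- tanh(gi[, i3, drop = FALSE] + r * ghn)
  h_new <- (1 - z) * n + z * h
  list(h = h_new, cache = list(x = x, h_prev = h, r = r, z = z, n = n,
                               ghn = ghn))
}

## Returns gradients w.r.t. inputs; parameter gradients accumulate into the
## `grads` environment (reference semantics).
.gru_backward <- function(dh_new, cache, Wi, Wh, grads, side, l) {
  r <- cache$r; z <- cache$z; n <- cache$n
  dz <- dh_new * (cache$h_prev - n)
  dn <- dh_new * (1 - z)
  dh_prev <- dh_new * z
  dn_pre <- dn * (1 - n * n)
  dr <- dn_pre * cache$ghn
  dghn <- dn_pre * r
  dz_pre <- dz * z * (1 - z)
  dr_pre <- dr * r * (1 - r)
  dgi <- cbind(dr_pre, dz_pre, dn_pre)
  dgh <- cbind(dr_pre, dz_pre, dghn)
  ki <- paste0(side, "_Wi_", l); kh <- paste0(side, "_Wh_", l)
  kbi <- paste0(side, "_bi_", l); kbh <- paste0(side, "_bh_", l)
  grads[[ki]] <- grads[[ki]] + crossprod(cache$x, dgi)
  grads[[kh]] <- grads[[kh]] + crossprod(cache$h_prev, dgh)
  grads[[kbi]] <- grads[[kbi]] + colSums(dgi)
  grads[[kbh]] <- grads[[kbh]] + colSums(dgh)
  list(dx = tcrossprod(dgi, Wi), dh_prev = dh_prev + tcrossprod(dgh, Wh))
}

## ---- forward / backward over a batch ------------------------------------

## batch: list(ids = [B x T] integer matrix (PAD=1), cond = length-B 0/1)
## Returns loss components, and (when `want_grads`) parameter gradients.
.cvae_batch <- function(params, cfg, batch, beta, eps = NULL,
                        want_grads = TRUE) {
  ids <- batch$ids; cond <- batch$cond
  B <- nrow(ids); Tt <- ncol(ids); H <- cfg$hidden_dim
  L <- cfg$n_gru_layers; Z <- cfg$latent_dim
  V <- nrow(params$emb)
  PAD <- 1L

  ## ----- encoder -----
  mask <- ids != PAD                       # [B x T]
  h_enc <- rep(list(matrix(0, B, H)), L)
  enc_caches <- vector("list", Tt)
  enc_hprev <- vector("list", Tt)
  for (t in seq_len(Tt)) {
    x <- cbind(params$emb[ids[, t], , drop = FALSE], cond)
    m <- mask[, t]
    caches_t <- vector("list", L)
    hprev_t <- vector("list", L)
    for (l in seq_len(L)) {
      res <- .gru_forward(x, h_enc[[l]], params[[paste0("enc_Wi_", l)]],
                          params[[paste0("enc_Wh_", l)]],
                          params[[paste0("enc_bi_", l)]],
                          params[[paste0("enc_bh_", l)]])
      caches_t[[l]] <- res$cache
      hprev_t[[l]] <- h_enc[[l]]
      h_new <- res$h
      ## padded steps carry the previous hidden state through unchanged
      h_enc[[l]] <- m * h_new + (1 - m) * h_enc[[l]]
      x <- h_enc[[l]]
    }
    enc_caches[[t]] <- caches_t
    enc_hprev[[t]] <- hprev_t
  }
  h_top <- h_enc[[L]]
  mu <- sweep(h_top %*% params$w_mu, 2L, params$b_mu, "+")
  logvar <- sweep(h_top %*% params$w_lv, 2L, params$b_lv, "+")
  sigma <- exp(0.5 * logvar)
  if (is.null(eps)) eps <- matrix(stats::rnorm(B * Z), B, Z)
  z <- mu + sigma * eps

  kl_row <- 0.5 * rowSums(mu^2 + sigma^2 - 1 - logvar)
  kl <- mean(kl_row)

  ## ----- decoder -----
  zc <- cbind(z, cond)
  h_dec <- vector("list", L)
  h0_pre <- vector("list", L)
  for (l in seq_len(L)) {
    pre <- sweep(zc %*% params[[paste0("dec0_W_", l)]], 2L,
                 params[[paste0("dec0_b_", l)]], "+")
    h0_pre[[l]] <- pre
    h_dec[[l]] <- tanh(pre)
  }
  h0_saved <- h_dec

  n_steps <- Tt - 1L
  tgt_mask <- ids[, -1L, drop = FALSE] != PAD     # predict tokens 2..T
  dec_caches <- vector("list", n_steps)
  probs_list <- if (want_grads) vector("list", n_steps) else NULL
  recon_rows <- numeric(B)
  for (t in seq_len(n_steps)) {
    x <- cbind(params$emb[ids[, t], , drop = FALSE], cond)
    caches_t <- vector("list", L)
    for (l in seq_len(L)) {
      res <- .gru_forward(x, h_dec[[l]], params[[paste0("dec_Wi_", l)]],
                          params[[paste0("dec_Wh_", l)]],
                          params[[paste0("dec_bi_", l)]],
                          params[[paste0("dec_bh_", l)]])
      caches_t[[l]] <- res$cache
      h_dec[[l]] <- res$h
      x <- h_dec[[l]]
    }
    dec_caches[[t]] <- caches_t
    logits <- sweep(h_dec[[L]] %*% params$w_out, 2L, params$b_out, "+")
    logits <- logits - apply(logits, 1L, max)
    expl <- exp(logits)
    probs <- expl / rowSums(expl)
    tgt <- ids[, t + 1L]
    p_tgt <- probs[cbind(seq_len(B), tgt)]
    recon_rows <- recon_rows -
      ifelse(tgt_mask[, t], log(pmax(p_tgt, 1e-12)), 0)
    if (want_grads) probs_list[[t]] <- probs
  }
  recon <- mean(recon_rows)
  total <- recon + beta * kl

  if (!want_grads) {
    return(list(recon = recon, kl = kl, beta = beta, total = total))
  }

  ## ----- backward -----
  grads <- list2env(rapply(params, function(m) m * 0, how = "replace"),
                    parent = emptyenv())
  demb <- grads$emb

  dh_dec <- rep(list(matrix(0, B, H)), L)
  for (t in rev(seq_len(n_steps))) {
    probs <- probs_list[[t]]
    tgt <- ids[, t + 1L]
    dlogits <- probs
    dlogits[cbind(seq_len(B), tgt)] <-
      dlogits[cbind(seq_len(B), tgt)] - 1
    dlogits <- dlogits * (tgt_mask[, t] / B)
    grads$w_out <- grads$w_out + crossprod(.dec_htop(dec_caches, t, L),
                                           dlogits)
    grads$b_out <- grads$b_out + colSums(dlogits)
    dh_dec[[L]] <- dh_dec[[L]] + tcrossprod(dlogits, params$w_out)
    dx_up <- NULL
    for (l in rev(seq_len(L))) {
      res <- .gru_backward(dh_dec[[l]] + (if (is.null(dx_up)) 0 else dx_up),
                           dec_caches[[t]][[l]],
                           params[[paste0("dec_Wi_", l)]],
                           params[[paste0("dec_Wh_", l)]], grads, "dec", l)
      dh_dec[[l]] <- res$dh_prev
      dx_up <- if (l > 1L) res$dx else NULL
      if (l == 1L) {
        dxe <- res$dx[, seq_len(cfg$embed_dim), drop = FALSE]
        rows <- ids[, t]
        for (b in seq_len(B)) {
          demb[rows[b], ] <- demb[rows[b], ] + dxe[b, ]
        }
      }
    }
  }
  ## initial decoder hidden states
  dz <- matrix(0, B, Z)
  for (l in seq_len(L)) {
    dpre <- dh_dec[[l]] * (1 - h0_saved[[l]]^2)
    grads[[paste0("dec0_W_", l)]] <- grads[[paste0("dec0_W_", l)]] +
      crossprod(cbind(z, cond), dpre)
    grads[[paste0("dec0_b_", l)]] <- grads[[paste0("dec0_b_", l)]] +
      colSums(dpre)
    dzc <- tcrossprod(dpre, params[[paste0("dec0_W_", l)]])
    dz <- dz + dzc[, seq_len(Z), drop = FALSE]
  }

  ## latent + KL
  dmu <- dz + beta * mu / B
  dlogvar <- dz * eps * 0.5 * sigma + beta * 0.5 * (sigma^2 - 1) / B
  grads$w_mu <- grads$w_mu + crossprod(h_top, dmu)
  grads$b_mu <- grads$b_mu + colSums(dmu)
  grads$w_lv <- grads$w_lv + crossprod(h_top, dlogvar)
  grads$b_lv <- grads$b_lv + colSums(dlogvar)
  dh_top <- tcrossprod(dmu, params$w_mu) + tcrossprod(dlogvar, params$w_lv)

  ## encoder BPTT
  dh_enc <- rep(list(matrix(0, B, H)), L)
  dh_enc[[L]] <- dh_top
  for (t in rev(seq_len(Tt))) {
    m <- mask[, t]
    dx_up <- NULL
    for (l in rev(seq_len(L))) {
      dh_t <- dh_enc[[l]] + (if (is.null(dx_up)) 0 else dx_up)
      dh_cell <- dh_t * m
      dh_carry <- dh_t * (1 - m)
      res <- .gru_backward(dh_cell, enc_caches[[t]][[l]],
                           params[[paste0("enc_Wi_", l)]],
                           params[[paste0("enc_Wh_", l)]], grads, "enc", l)
      dh_enc[[l]] <- res$dh_prev + dh_carry
      dx_up <- if (l > 1L) res$dx else NULL
      if (l == 1L) {
        dxe <- res$dx[, seq_len(cfg$embed_dim), drop = FALSE]
        rows <- ids[, t]
        for (b in seq_len(B)) {
          demb[rows[b], ] <- demb[rows[b], ] + dxe[b, ]
        }
      }
    }
  }
  grads$emb <- demb
  glist <- as.list(grads)[names(params)]
  list(recon = recon, kl = kl, beta = beta, total = total, grads = glist)
}

## hidden state of the decoder's top layer after step t (from its cache: the
## cell output is the next step's h_prev; recompute from cache directly)
.dec_htop <- function(dec_caches, t, L) {
  cache <- dec_caches[[t]][[L]]
  (1 - cache$z) * cache$n + cache$z * cache$h_prev
}

## ---- Adam ----------------------------------------------------------------

.adam_init <- function(params) {
  list(m = rapply(params, function(x) x * 0, how = "replace"),
       v = rapply(params, function(x) x * 0, how = "replace"),
       t = 0L)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, clip = NULL) {
  if (!is.null(clip)) {
    gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
    if (is.finite(gnorm) && gnorm > clip) {
      grads <- rapply(grads, function(g) g * (clip / gnorm), how = "replace")
    }
  }
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / corr1) / (sqrt(state$v[[k]] / corr2) + eps)
  }
  list(params = params, state = state)
}

## ---- training ------------------------------------------------------------

#' Train a conditional SMILES VAE
#'
#' Trains the GRU encoder/decoder CVAE on `(smiles, condition)` pairs with
#' teacher forcing, the reparameterization trick, Adam, and cyclic KL
#' annealing. Fully seeded: the same configuration and data reproduce the
#' loss history exactly.
#'
#' @param data Data frame with columns `smiles` and `condition` (0/1), or a
#'   character vector (condition then defaults to 1).
#' @param config A [cvae_config()].
#' @return An object of class `"cvae_model"`: parameters, vocabulary,
#'   config, and a per-epoch `history` tibble (`epoch`, `recon`, `kl`,
#'   `beta`, `total`).
#' @export
train_cvae <- function(data, config = cvae_config()) {
  if (is.character(data)) {
    data <- tibble::tibble(smiles = data, condition = 1)
  }
  stopifnot(all(c("smiles", "condition") %in% names(data)),
            all(data$condition %in% c(0, 1)))
  too_long <- nchar(data$smiles) + 2L > config$max_len
  if (any(too_long)) {
    message("Excluding ", sum(too_long), " sequence(s) longer than max_len.")
    data <- data[!too_long, , drop = FALSE]
  }
  stopifnot(nrow(data) >= 2L)

  vocab <- build_vocabulary(data$smiles)
  seqs <- tokenize_smiles(data$smiles, vocab, config$max_len)
  n <- length(seqs)
  n_batches <- ceiling(n / config$batch_size)
  total_steps <- config$epochs * n_batches

  params <- with_seed(config$seed,
                      .cvae_init_params(length(vocab$id_to_token), config))
  state <- .adam_init(params)
  history <- vector("list", config$epochs)
  step <- 0L

  for (epoch in seq_len(config$epochs)) {
    ord <- with_seed(config$seed * 1000L + epoch, sample.int(n))
    ep_recon <- 0; ep_kl <- 0; ep_beta <- 0
    for (b in seq_len(n_batches)) {
      idx <- ord[(((b - 1L) * config$batch_size + 1L)):min(b * config$batch_size, n)]
      batch <- list(ids = pad_batch(seqs[idx]), cond = data$condition[idx])
      beta <- kl_anneal_weight(step, total_steps, config$anneal)
      eps <- with_seed(config$seed * 100000L + step,
                       matrix(stats::rnorm(length(idx) * config$latent_dim),
                              length(idx), config$latent_dim))
      out <- .cvae_batch(params, config, batch, beta, eps = eps)
      if (!is.finite(out$total)) {
        stop("Non-finite loss at epoch ", epoch, ", batch ", b,
             " (recon = ", out$recon, ", kl = ", out$kl, ").", call. = FALSE)
      }
      upd <- .adam_step(params, out$grads, state, config$lr,
                        clip = config$grad_clip)
      params <- upd$params; state <- upd$state
      w <- length(idx) / n
      ep_recon <- ep_recon + w * out$recon
      ep_kl <- ep_kl + w * out$kl
      ep_beta <- ep_beta + out$beta / n_batches
      step <- step + 1L
    }
    history[[epoch]] <- tibble::tibble(epoch = epoch, recon = ep_recon,
                                       kl = ep_kl, beta = ep_beta,
                                       total = ep_recon + ep_beta * ep_kl)
  }

  structure(
    list(params = params, vocab = vocab, config = config,
         history = dplyr::bind_rows(history),
         training_smiles = unique(data$smiles)),
    class = "cvae_model"
  )
}

#' @export
print.cvae_model <- function(x, ...) {
  cfg <- x$config
  cat("SMILES CVAE: ", cfg$n_gru_layers, "-layer GRU, hidden ",
      cfg$hidden_dim, ", latent ", cfg$latent_dim, ", vocab ",
      length(x$vocab$id_to_token), ", trained ", cfg$epochs, " epochs\n",
      sep = "")
  invisible(x)
}

#' CVAE loss on held-out data
#'
#' Evaluates the ELBO terms (teacher-forced per-sequence token cross-entropy,
#' closed-form Gaussian KL, total = recon + beta * kl) without updating the
#' model. The posterior mean is used (no sampling noise).
#'
#' @param model A `"cvae_model"`.
#' @param data Data frame with `smiles` and `condition`.
#' @param beta KL weight for the reported total.
#' @return A one-row tibble with `recon`, `kl`, `beta`, `total`.
#' @export
cvae_loss <- function(model, data, beta = 1.0) {
  stopifnot(inherits(model, "cvae_model"))
  seqs <- tokenize_smiles(data$smiles, model$vocab, model$config$max_len)
  batch <- list(ids = pad_batch(seqs), cond = data$condition)
  Z <- model$config$latent_dim
  out <- .cvae_batch(model$params, model$config, batch, beta,
                     eps = matrix(0, length(seqs), Z), want_grads = FALSE)
  tibble::tibble(recon = out$recon, kl = out$kl, beta = out$beta,
                 total = out$total)
}

## Closed-form KL of N(mu, sigma^2) against N(0, 1), summed over dimensions.
gaussian_kl <- function(mu, logvar) {
  0.5 * sum(mu^2 + exp(logvar) - 1 - logvar)
}

## ---- sampling / reconstruction ------------------------------------------

.decode_step_state <- function(model, h_dec, ids_prev, cond) {
  params <- model$params; cfg <- model$config
  x <- cbind(params$emb[ids_prev, , drop = FALSE], cond)
  for (l in seq_len(cfg$n_gru_layers)) {
    res <- .gru_forward(x, h_dec[[l]], params[[paste0("dec_Wi_", l)]],
                        params[[paste0("dec_Wh_", l)]],
                        params[[paste0("dec_bi_", l)]],
                        params[[paste0("dec_bh_", l)]])
    h_dec[[l]] <- res$h
    x <- res$h
  }
  logits <- sweep(h_dec[[cfg$n_gru_layers]] %*% params$w_out, 2L,
                  params$b_out, "+")
  list(h = h_dec, logits = logits)
}

.init_decoder_hidden <- function(model, z, cond) {
  params <- model$params
  zc <- cbind(z, cond)
  lapply(seq_len(model$config$n_gru_layers), function(l) {
    tanh(sweep(zc %*% params[[paste0("dec0_W_", l)]], 2L,
               params[[paste0("dec0_b_", l)]], "+"))
  })
}

.decode_autoregressive <- function(model, z, cond, greedy, temperature) {
  cfg <- model$config; vocab <- model$vocab
  B <- nrow(z)
  h <- .init_decoder_hidden(model, z, cond)
  ids_prev <- rep(vocab$specials[["BOS"]], B)
  done <- rep(FALSE, B)
  out <- vector("list", B)
  for (t in seq_len(cfg$max_len - 1L)) {
    st <- .decode_step_state(model, h, ids_prev, cond)
    h <- st$h
    if (greedy) {
      nxt <- max.col(st$logits, ties.method = "first")
    } else {
      logits <- st$logits / temperature
      logits <- logits - apply(logits, 1L, max)
      probs <- exp(logits)
      probs <- probs / rowSums(probs)
      nxt <- vapply(seq_len(B), function(b) {
        sample.int(ncol(probs), 1L, prob = probs[b, ])
      }, integer(1))
    }
    for (b in seq_len(B)) {
      if (done[b]) next
      if (nxt[b] == vocab$specials[["EOS"]] ||
          nxt[b] == vocab$specials[["PAD"]]) {
        done[b] <- TRUE
      } else {
        out[[b]] <- c(out[[b]], nxt[b])
      }
    }
    if (all(done)) break
    ids_prev <- nxt
  }
  vapply(out, function(ids) {
    if (is.null(ids)) "" else paste(vocab$id_to_token[ids], collapse = "")
  }, character(1))
}

#' Sample ions from a trained CVAE
#'
#' Draws latent vectors from the standard-normal prior, concatenates the
#' requested condition, and decodes autoregressively (multinomial sampling
#' at the given temperature) until EOS or the model's `max_len`. Outputs are
#' raw strings and may be invalid SMILES; validity is measured downstream by
#' [generation_metrics()] and enforced by [apply_post_filter()].
#'
#' @param model A `"cvae_model"`.
#' @param n Number of samples (0 returns an empty character vector).
#' @param condition Desired condition, 0 or 1 (1 = IL-like).
#' @param seed Integer seed; the same seed reproduces the samples exactly.
#' @param temperature Softmax temperature (default 1.0).
#' @return Character vector of length `n`.
#' @export
sample_ions <- function(model, n, condition = 1, seed = 1L,
                        temperature = 1.0) {
  stopifnot(inherits(model, "cvae_model"), n >= 0L,
            condition %in% c(0, 1), temperature > 0)
  if (n == 0L) return(character(0))
  with_seed(seed, {
    z <- matrix(stats::rnorm(n * model$config$latent_dim), n,
                model$config$latent_dim)
    .decode_autoregressive(model, z, rep(condition, n), greedy = FALSE,
                           temperature = temperature)
  })
}

## Posterior-mean latent code for given sequences.
.encode_mean <- function(model, smiles, condition) {
  params <- model$params; cfg <- model$config
  seqs <- tokenize_smiles(smiles, model$vocab, cfg$max_len)
  ids <- pad_batch(seqs)
  B <- nrow(ids); H <- cfg$hidden_dim; L <- cfg$n_gru_layers
  mask <- ids != 1L
  h_enc <- rep(list(matrix(0, B, H)), L)
  for (t in seq_len(ncol(ids))) {
    x <- cbind(params$emb[ids[, t], , drop = FALSE], condition)
    m <- mask[, t]
    for (l in seq_len(L)) {
      res <- .gru_forward(x, h_enc[[l]], params[[paste0("enc_Wi_", l)]],
                          params[[paste0("enc_Wh_", l)]],
                          params[[paste0("enc_bi_", l)]],
                          params[[paste0("enc_bh_", l)]])
      h_enc[[l]] <- m * res$h + (1 - m) * h_enc[[l]]
      x <- h_enc[[l]]
    }
  }
  sweep(h_enc[[L]] %*% params$w_mu, 2L, params$b_mu, "+")
}

#' Reconstruction accuracy
#'
#' Encodes each test string with its condition, decodes greedily from the
#' posterior mean, and counts a success when the decoded string matches the
#' input as the same molecule (canonical-form comparison; unparseable
#' decodes only match as exact strings).
#'
#' @param model A `"cvae_model"`.
#' @param data Data frame with `smiles` and `condition`.
#' @return Fraction of correctly reconstructed sequences in `[0, 1]`.
#' @export
reconstruction_accuracy <- function(model, data) {
  stopifnot(nrow(data) >= 1L)
  mu <- .encode_mean(model, data$smiles, data$condition)
  dec <- .decode_autoregressive(model, mu, data$condition, greedy = TRUE,
                                temperature = 1.0)
  can_in <- ob_canonical(data$smiles)
  can_out <- ob_canonical(dec)
  same <- ifelse(!is.na(can_in) & !is.na(can_out),
                 can_in == can_out, dec == data$smiles)
  mean(same)
}
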