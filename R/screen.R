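#' Generation metrics
#'
#' The standard generative-chemistry metrics over a sample of raw generated
#' strings: validity is the parseable fraction of all samples; uniqueness is
#' the fraction of distinct canonical structures among the valid ones;
#' novelty is the fraction of those unique structures absent from the
#' (canonicalized) training set. With no valid samples, uniqueness and
#' novelty are undefined and reported as `NA`.
#'
#' @param samples Character vector of generated strings (non-empty).
#' @param training_set Character vector of training SMILES (may be empty).
#' @return One-row tibble: `validity`, `uniqueness`, `novelty`, `n_sampled`.
#' @export
generation_metrics <- function(samples, training_set = character(0)) {
  stopifnot(length(samples) >= 1L)
  can <- ob_canonical(samples)
  valid <- can[!is.na(can)]
  validity <- length(valid) / length(samples)
  if (length(valid) == 0L) {
    return(tibble::tibble(validity = 0, uniqueness = NA_real_,
                          novelty = NA_real_, n_sampled = length(samples)))
  }
  uniq <- unique(valid)
  train_can <- unique(ob_canonical(training_set))
  train_can <- train_can[!is.na(train_can)]
  tibble::tibble(
    validity = validity,
    uniqueness = length(uniq) / length(valid),
    novelty = mean(!uniq %in% train_can),
    n_sampled = length(samples)
  )
}

#' Combine cations and anions exhaustively
#'
#' Full Cartesian product of the two ion lists in deterministic
#' cation-major order. Inputs are expected to be deduplicated by canonical
#' SMILES; duplicates are reported with a warning and collapsed, so the
#' output always has `|unique cations| x |unique anions|` unique pairs.
#'
#' @param cations,anions Character vectors of SMILES or data frames with a
#'   `smiles` column (non-empty).
#' @return Tibble with columns `cation_smiles`, `anion_smiles`.
#' @export
combine_ions <- function(cations, anions) {
  get_smiles <- function(x, what) {
    s <- if (is.data.frame(x)) x$smiles else as.character(x)
    if (length(s) == 0L) stop("Empty ", what, " list.", call. = FALSE)
    can <- ob_canonical(s)
    if (anyNA(can)) stop("Unparseable ", what, "(s).", call. = FALSE)
    if (anyDuplicated(can)) {
      warning("Duplicate canonical ", what, "(s) in input; deduplicated (",
              length(unique(can)), " unique).", call. = FALSE)
      can <- unique(can)
    }
    can
  }
  cs <- get_smiles(cations, "cation")
  as <- get_smiles(anions, "anion")
  tibble::tibble(
    cation_smiles = rep(cs, each = length(as)),
    anion_smiles = rep(as, times = length(cs))
  )
}

#' Rank pairs by predicted melting point and select the top candidates
#'
#' Predicts the melting point of every pair, sorts ascending (ties broken
#' by the canonical pair string for determinism) and keeps the `top_n`
#' lowest-melting candidates. Pairs whose featurization fails are excluded
#' before ranking and counted in `attr(, "n_failed")`.
#'
#' @param pairs Tibble from [combine_ions()].
#' @param mpt_model An `"mpt_model"` from [train_mpt()].
#' @param top_n Number of pairs to keep (`<=` number of rankable pairs).
#' @return A tibble of class `"screen_result"` with `rank`,
#'   `cation_smiles`, `anion_smiles`, `pred_mpt_K`, sorted ascending.
#' @export
rank_and_select <- function(pairs, mpt_model, top_n) {
  stopifnot(is.data.frame(pairs),
            all(c("cation_smiles", "anion_smiles") %in% names(pairs)),
            inherits(mpt_model, "mpt_model"))
  pred <- rep(NA_real_, nrow(pairs))
  ok <- rep(TRUE, nrow(pairs))
  res <- try(predict_mpt(mpt_model, pairs$cation_smiles, pairs$anion_smiles),
             silent = TRUE)
  if (inherits(res, "try-error")) {
    ## fall back to per-pair prediction so single failures are excluded
    for (i in seq_len(nrow(pairs))) {
      p <- try(predict_mpt(mpt_model, pairs$cation_smiles[i],
                           pairs$anion_smiles[i]), silent = TRUE)
      if (inherits(p, "try-error")) ok[i] <- FALSE else pred[i] <- p
    }
  } else {
    pred <- res
  }
  n_failed <- sum(!ok)
  stopifnot(top_n <= sum(ok))
  ranked <- tibble::tibble(
    cation_smiles = pairs$cation_smiles[ok],
    anion_smiles = pairs$anion_smiles[ok],
    pred_mpt_K = pred[ok]
  ) |>
    dplyr::arrange(.data$pred_mpt_K, .data$cation_smiles,
                   .data$anion_smiles) |>
    utils::head(top_n)
  out <- dplyr::bind_cols(tibble::tibble(rank = seq_len(nrow(ranked))),
                          ranked)
  class(out) <- c("screen_result", class(out))
  attr(out, "n_failed") <- n_failed
  out
}

#' Project structures into a 2-D chemical space
#'
#' Embeds molecules by the Jaccard (Tanimoto) distances between their
#' extended-connectivity fingerprints. The default method is principal
#' coordinates analysis (classical multidimensional scaling), which is
#' deterministic and maps duplicate structures to identical coordinates;
#' `method = "nmds"` uses seeded non-metric MDS instead. Unparseable
#' entries are dropped and counted in `attr(, "n_dropped")`.
#'
#' @param smiles Character vector (at least 10 parseable structures).
#' @param seed Integer seed (used by the NMDS method; PCoA is
#'   deterministic).
#' @param method `"pcoa"` (default) or `"nmds"`.
#' @param radius,nbits Fingerprint settings, see [compute_ecfp()].
#' @return Tibble with `smiles`, `x`, `y`.
#' @export
project_chemical_space <- function(smiles, seed = 1L,
                                   method = c("pcoa", "nmds"),
                                   radius = 2L, nbits = 2048L) {
  method <- match.arg(method)
  can <- ob_canonical(smiles)
  keep <- !is.na(can)
  stopifnot(sum(keep) >= 10L)
  fp <- compute_ecfp(can[keep], radius = radius, nbits = nbits)
  d <- vegan::vegdist(fp, method = "jaccard", binary = TRUE)
  coords <- if (method == "pcoa") {
    stats::cmdscale(d, k = 2L)
  } else {
    fit <- with_seed(seed, vegan::monoMDS(d, k = 2L))
    fit$points
  }
  out <- tibble::tibble(smiles = smiles[keep],
                        x = coords[, 1L], y = coords[, 2L])
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Run the full ion-design workflow
#'
#' Orchestrates the end-to-end protocol on synthetic corpora: build IL-like
#' and decoy corpora, train cation/anion scorers, train the two conditional
#' VAEs, sample candidates at condition 1, post-filter them, train the
#' melting-point model, combine the retained cations and anions
#' exhaustively, and rank the pairs by predicted melting point. All stages
#' are seeded from `seed`; any failure aborts with the stage name, and
#' artifacts (models, metrics, reports) computed so far are attached to the
#' error condition where available.
#'
#' @param n_per_class Corpus size per class and ion kind (default 400).
#' @param n_candidates Post-filtered ions of each kind to carry into
#'   combination (default 20).
#' @param top_fraction Fraction of the combined pairs to keep (default 0.5).
#' @param n_mpt Synthetic melting-point records (default 600).
#' @param seed Master seed.
#' @param cvae Optional named list overriding [cvae_config()] fields for the
#'   two generators (a compact model is used by default).
#' @param n_sample Raw samples drawn per ion kind before post-filtering
#'   (default 400).
#' @param components Optional pre-trained components: a list with any of
#'   `scorer_cation`, `scorer_anion`, `cvae_cation`, `cvae_anion`, `mpt`.
#'   Supplied components are validated and reused instead of retrained.
#' @param out_dir Optional directory; when given, ranked pairs, metrics and
#'   a JSON run manifest (seeds, model identifiers, package version) are
#'   written there.
#' @return A list with `result` (the `screen_result`), `models`, `metrics`
#'   and `manifest`.
#' @export
run_workflow <- function(n_per_class = 400L, n_candidates = 20L,
                         top_fraction = 0.5, n_mpt = 600L, seed = 1L,
                         cvae = list(), n_sample = 400L,
                         components = list(), out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("Stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  models <- list()
  metrics <- list()

  corpora <- stage("fixtures", {
    lapply(c(cation = "cation", anion = "anion"), function(kind) {
      list(il = make_il_like_corpus(n_per_class, seed, kind),
           decoy = make_decoy_corpus(n_per_class, seed + 1L, kind))
    })
  })

  for (kind in c("cation", "anion")) {
    key <- paste0("scorer_", kind)
    models[[key]] <- stage("scorer", {
      if (!is.null(components[[key]])) {
        m <- components[[key]]
        if (!inherits(m, "ion_scorer") || m$ion_kind != kind) {
          stop("components$", key, " is not an ion_scorer for ", kind)
        }
        m
      } else {
        ds <- build_scorer_dataset(corpora[[kind]]$il, corpora[[kind]]$decoy,
                                   seed = seed)
        feats <- select_features(ds, k = 25L, seed = seed)
        m <- train_scorer(ds, feats, alpha = 0.2, ion_kind = kind,
                          seed = seed)
        metrics[[paste0("scorer_", kind)]] <- evaluate_scorer(m, ds, "test")
        m
      }
    })
  }

  cvae_defaults <- list(embed_dim = 48L, hidden_dim = 64L, n_gru_layers = 1L,
                        latent_dim = 16L, lr = 3e-3, batch_size = 128L,
                        epochs = 20L, max_len = 64L)
  cvae_args <- utils::modifyList(cvae_defaults, cvae)

  sampled <- list()
  for (kind in c("cation", "anion")) {
    key <- paste0("cvae_", kind)
    models[[key]] <- stage("cvae", {
      if (!is.null(components[[key]])) {
        m <- components[[key]]
        if (!inherits(m, "cvae_model")) stop("components$", key,
                                             " is not a cvae_model")
        m
      } else {
        dat <- tibble::tibble(
          smiles = c(corpora[[kind]]$il$smiles, corpora[[kind]]$decoy$smiles),
          condition = rep(c(1, 0), c(nrow(corpora[[kind]]$il),
                                     nrow(corpora[[kind]]$decoy)))
        )
        cfg <- do.call(cvae_config, c(cvae_args, list(seed = seed)))
        train_cvae(dat, cfg)
      }
    })
    sampled[[kind]] <- stage("sample", {
      sample_ions(models[[key]], n_sample, condition = 1,
                  seed = seed + 10L)
    })
    metrics[[paste0("generation_", kind)]] <- stage("metrics", {
      generation_metrics(sampled[[kind]],
                         models[[key]]$training_smiles)
    })
  }

  filtered <- list()
  for (kind in c("cation", "anion")) {
    res <- stage("postfilter", {
      apply_post_filter(sampled[[kind]], kind,
                        models[[paste0("scorer_", kind)]])
    })
    kept <- dplyr::distinct(res$kept, .data$smiles, .keep_all = TRUE)
    if (nrow(kept) < n_candidates) {
      stop("Stage 'postfilter' failed: only ", nrow(kept), " unique ", kind,
           "(s) survived post-filtering; requested ", n_candidates,
           ". Increase n_sample.", call. = FALSE)
    }
    filtered[[kind]] <- kept[seq_len(n_candidates), , drop = FALSE]
    metrics[[paste0("postfilter_", kind)]] <- res$report$counts
  }

  models$mpt <- stage("mpt", {
    if (!is.null(components$mpt)) {
      m <- components$mpt
      if (!inherits(m, "mpt_model")) stop("components$mpt is not an mpt_model")
      m
    } else {
      mdat <- make_synthetic_mpt_dataset(n_mpt, seed + 20L)
      m <- train_mpt(mdat, backend = "random_forest", seed = seed)
      metrics$mpt <- m$metrics
      m
    }
  })

  pairs <- stage("combine", {
    combine_ions(filtered$cation$smiles, filtered$anion$smiles)
  })
  top_n <- max(1L, floor(nrow(pairs) * top_fraction))
  result <- stage("rank", rank_and_select(pairs, models$mpt, top_n))

  manifest <- list(
    package_version = as.character(utils::packageVersion("ilgen")),
    seed = seed, n_per_class = n_per_class, n_candidates = n_candidates,
    n_sample = n_sample, top_fraction = top_fraction, n_pairs = nrow(pairs),
    n_selected = nrow(result),
    descriptor_set = DESCRIPTOR_SET_VERSION,
    cvae_config = cvae_args,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(result, file.path(out_dir, "ranked_pairs.csv"))
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(result = result, models = models, metrics = metrics,
       manifest = manifest, candidates = filtered)
}
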