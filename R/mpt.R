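#' Featurize a cation-anion pair
#'
#' Computes the frozen descriptor set for each pair. The default mode,
#' `"concat"`, computes descriptors per ion (once per unique ion) and
#' concatenates a cation block and an anion block; the blocks are assigned
#' by formal-charge sign, not by argument position, so the vector is
#' invariant to fragment order. `mode = "combined"` instead computes one
#' descriptor vector on the combined two-fragment salt (dot-joined, sorted
#' canonical fragments); there, additive descriptors (molecular weight,
#' donor counts, element counts) equal the sum of the per-ion values.
#'
#' @param cation_smiles,anion_smiles Character vectors of equal length.
#' @param mode `"concat"` (default) or `"combined"`.
#' @return A tibble: `cation_smiles`, `anion_smiles`, `pair_smiles`, then
#'   descriptor columns (`cation_*`/`anion_*` in concat mode).
#' @export
featurize_pairs <- function(cation_smiles, anion_smiles,
                            mode = c("concat", "combined")) {
  mode <- match.arg(mode)
  stopifnot(length(cation_smiles) == length(anion_smiles),
            length(cation_smiles) >= 1L)
  cc <- ob_canonical(cation_smiles)
  ca <- ob_canonical(anion_smiles)
  bad <- is.na(cc) | is.na(ca)
  if (any(bad)) {
    stop("Unparseable ion(s) in pair featurization: ",
         paste(utils::head(unique(c(cation_smiles[is.na(cc)],
                                    anion_smiles[is.na(ca)])), 3L),
               collapse = ", "), call. = FALSE)
  }
  ## assign fragments to the cation/anion roles by charge sign so swapped
  ## arguments produce identical features
  uall <- unique(c(cc, ca))
  q <- net_formal_charge(uall)
  qc <- q[match(cc, uall)]
  qa <- q[match(ca, uall)]
  swap <- qc < 0L & qa > 0L
  tmp <- cc[swap]; cc[swap] <- ca[swap]; ca[swap] <- tmp
  pair <- paste(cc, ca, sep = ".")
  head_cols <- tibble::tibble(cation_smiles = cc, anion_smiles = ca,
                              pair_smiles = pair)

  if (mode == "combined") {
    key <- ifelse(cc <= ca, pair, paste(ca, cc, sep = "."))
    ukey <- unique(key)
    desc <- compute_descriptors(ukey)
    out <- desc[match(key, ukey), , drop = FALSE]
    return(dplyr::bind_cols(head_cols,
                            out[, setdiff(names(out), "smiles")]))
  }

  uc <- unique(cc)
  ua <- unique(ca)
  dc <- compute_descriptors(uc)
  da <- compute_descriptors(ua)
  dc <- dc[match(cc, uc), setdiff(names(dc), "smiles"), drop = FALSE]
  da <- da[match(ca, ua), setdiff(names(da), "smiles"), drop = FALSE]
  names(dc) <- paste0("cation_", names(dc))
  names(da) <- paste0("anion_", names(da))
  dplyr::bind_cols(head_cols, dc, da)
}

#' Train a melting-point regressor
#'
#' Fits a regressor from combined pair descriptors to melting point in
#' kelvin on a seeded 80:20 train/test split, reporting held-out RMSE, MAE
#' and R-squared. Backends: `"random_forest"` (default, no extra
#' dependencies), `"xgboost"` (gradient boosting), and
#' `"tabular_foundation"` — a transformer-based tabular-foundation backend
#' that requires downloading pretrained weights and is therefore not
#' bundled; requesting it raises an informative error suggesting the
#' default.
#'
#' @param data Data frame with columns `cation_smiles`, `anion_smiles`,
#'   `mpt_K` (at least 50 rows).
#' @param backend Backend name.
#' @param seed Integer seed for the split and the backend's randomness.
#' @param train_fraction Training fraction (default 0.8).
#' @param num_trees Trees for the forest / boosting rounds (default 500).
#' @param mode Pair featurization mode passed to [featurize_pairs()];
#'   `"concat"` (default) keeps cation- and anion-resolved descriptor
#'   blocks, `"combined"` featurizes the dot-joined salt.
#' @return An object of class `"mpt_model"`; held-out metrics are in
#'   `$metrics` and the split indices in `$split`.
#' @export
train_mpt <- function(data, backend = c("random_forest", "xgboost",
                                        "tabular_foundation"),
                      seed = 1L, train_fraction = 0.8, num_trees = 500L,
                      mode = c("concat", "combined")) {
  backend <- match.arg(backend)
  mode <- match.arg(mode)
  stopifnot(is.data.frame(data), nrow(data) >= 50L,
            all(c("cation_smiles", "anion_smiles", "mpt_K") %in% names(data)))
  if (backend == "tabular_foundation") {
    stop("The tabular-foundation backend needs pretrained transformer ",
         "weights that are not bundled with this package; use backend = ",
         "\"random_forest\" (default) or \"xgboost\".", call. = FALSE)
  }
  if (backend == "xgboost" && !requireNamespace("xgboost", quietly = TRUE)) {
    stop("Package 'xgboost' is not installed; use backend = ",
         "\"random_forest\".", call. = FALSE)
  }

  feats <- featurize_pairs(data$cation_smiles, data$anion_smiles, mode = mode)
  feat_cols <- setdiff(names(feats),
                       c("cation_smiles", "anion_smiles", "pair_smiles"))
  x <- as.matrix(feats[, feat_cols])
  y <- data$mpt_K

  n <- nrow(x)
  test_idx <- with_seed(seed, sample.int(n, round(n * (1 - train_fraction))))
  train_idx <- setdiff(seq_len(n), test_idx)

  fit <- if (backend == "random_forest") {
    with_seed(seed, randomForest::randomForest(
      x = x[train_idx, , drop = FALSE], y = y[train_idx],
      ntree = num_trees))
  } else {
    with_seed(seed, xgboost::xgboost(
      x = x[train_idx, , drop = FALSE], y = y[train_idx],
      nrounds = num_trees, max_depth = 6L, learning_rate = 0.1,
      nthreads = 1L, verbosity = 0L))
  }

  model <- structure(
    list(backend = backend, fit = fit, feature_cols = feat_cols,
         descriptor_set = DESCRIPTOR_SET_VERSION, seed = seed,
         num_trees = num_trees, mode = mode,
         split = list(train = train_idx, test = test_idx)),
    class = "mpt_model"
  )
  pred_test <- .mpt_predict_matrix(model, x[test_idx, , drop = FALSE])
  model$metrics <- evaluate_mpt(pred_test, y[test_idx])
  model
}

.mpt_predict_matrix <- function(model, x) {
  if (model$backend == "random_forest") {
    unname(stats::predict(model$fit, x))
  } else {
    stats::predict(model$fit, x)
  }
}

#' @export
print.mpt_model <- function(x, ...) {
  cat("Melting-point model (", x$backend, "), ", length(x$feature_cols),
      " pair descriptors\n", sep = "")
  if (!is.null(x$metrics)) {
    cat(sprintf("  held-out RMSE %.1f K, MAE %.1f K, R2 %.3f\n",
                x$metrics$rmse, x$metrics$mae, x$metrics$r2))
  }
  invisible(x)
}

#' Predict melting points for cation-anion pairs
#'
#' Batched prediction preserving input order; invariant to fragment order.
#'
#' @param model An `"mpt_model"`.
#' @param cation_smiles,anion_smiles Equal-length SMILES vectors.
#' @return Numeric vector of predicted melting points in kelvin.
#' @export
predict_mpt <- function(model, cation_smiles, anion_smiles) {
  stopifnot(inherits(model, "mpt_model"))
  feats <- featurize_pairs(cation_smiles, anion_smiles,
                           mode = model$mode %||% "concat")
  x <- as.matrix(feats[, model$feature_cols])
  .mpt_predict_matrix(model, x)
}

#' @export
predict.mpt_model <- function(object, newdata, ...) {
  predict_mpt(object, newdata$cation_smiles, newdata$anion_smiles)
}

#' Regression metrics for melting-point prediction
#'
#' Standard definitions: root-mean-squared error, mean absolute error and
#' the coefficient of determination `R2 = 1 - SS_res / SS_tot`. RMSE is
#' always at least MAE.
#'
#' @param predictions,truths Equal-length numeric vectors (length >= 2).
#' @return One-row tibble with `rmse`, `mae`, `r2`, `n`.
#' @export
evaluate_mpt <- function(predictions, truths) {
  stopifnot(length(predictions) == length(truths), length(truths) >= 2L,
            all(is.finite(predictions)), all(is.finite(truths)))
  if (stats::sd(truths) == 0) {
    stop("R-squared is undefined for constant truth values.", call. = FALSE)
  }
  err <- predictions - truths
  tibble::tibble(
    rmse = sqrt(mean(err^2)),
    mae = mean(abs(err)),
    r2 = 1 - sum(err^2) / sum((truths - mean(truths))^2),
    n = length(truths)
  )
}

#' @method glance mpt_model
#' @export
glance.mpt_model <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(backend = x$backend, n_features = length(x$feature_cols),
                   num_trees = x$num_trees, seed = x$seed,
                   descriptor_set = x$descriptor_set),
    x$metrics
  )
}

#' @method tidy mpt_model
#' @export
tidy.mpt_model <- function(x, ...) {
  if (x$backend == "random_forest") {
    imp <- randomForest::importance(x$fit)
    tibble::tibble(term = rownames(imp), importance = imp[, 1L]) |>
      dplyr::arrange(dplyr::desc(.data$importance))
  } else {
    im <- xgboost::xgb.importance(model = x$fit)
    tibble::tibble(term = im$Feature, importance = im$Gain)
  }
}
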