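#' Label smoothing
#'
#' Softens hard 0/1 labels to `(1 - alpha) * y + alpha / n_classes`,
#' injecting a controlled amount of label noise so a classifier trained on
#' imperfect labels does not saturate its probabilities. With the default
#' `alpha = 0.2` and two classes, 1 becomes 0.9 and 0 becomes 0.1; for two
#' classes the smoothed labels of the two targets always sum to 1.
#'
#' @param y Numeric vector of hard labels in `{0, 1}`.
#' @param alpha Smoothing strength in `[0, 1)`.
#' @param n_classes Number of label classes (2 for binary).
#' @return Numeric vector of smoothed labels in `(0, 1)` (or `{0,1}` at
#'   `alpha = 0`).
#' @examples
#' smooth_labels(c(1, 0))          # 0.9, 0.1
#' @export
smooth_labels <- function(y, alpha = 0.2, n_classes = 2L) {
  stopifnot(all(y %in% c(0, 1)), alpha >= 0, alpha < 1, n_classes >= 2L)
  (1 - alpha) * y + alpha / n_classes
}

#' Assemble a balanced ion-scorer dataset
#'
#' Labels every IL-derived ion 1 and a seeded, equally sized uniform sample
#' of the general-ion corpus 0, computes the frozen descriptor set for all
#' of them, and assigns a seeded stratified 80:20 train/test split.
#'
#' @param il_ions,general_ions Data frames with a `smiles` column (and the
#'   same ion kind), or character vectors of SMILES. `general_ions` must
#'   contain at least as many rows as `il_ions`.
#' @param seed Integer seed controlling the balancing sample and the split.
#' @param train_fraction Fraction of each class assigned to the training
#'   split (default 0.8).
#' @return A tibble with columns `smiles`, `label` (hard 0/1), `split`
#'   (`"train"`/`"test"`) and one column per descriptor; descriptor names
#'   are recorded in `attr(, "feature_cols")`.
#' @export
build_scorer_dataset <- function(il_ions, general_ions, seed,
                                 train_fraction = 0.8) {
  get_smiles <- function(x) if (is.data.frame(x)) x$smiles else as.character(x)
  il <- get_smiles(il_ions)
  gen <- get_smiles(general_ions)
  stopifnot(length(il) >= 1L, train_fraction > 0, train_fraction < 1)
  if (length(gen) < length(il)) {
    stop("Need at least as many general ions as IL ions for balancing (",
         length(gen), " < ", length(il), ").", call. = FALSE)
  }
  gen_sample <- gen[with_seed(seed, sample.int(length(gen), length(il)))]
  smiles <- c(il, gen_sample)
  label <- rep(c(1, 0), c(length(il), length(gen_sample)))

  desc <- compute_descriptors(smiles)
  fails <- attr(desc, "descriptor_failures")
  if (!is.null(fails)) {
    bad <- smiles %in% unique(fails$smiles)
    message("Dropping ", sum(bad), " ion(s) with descriptor failures.")
    desc <- desc[!bad, , drop = FALSE]
    label <- label[!bad]
  }

  split <- rep("train", nrow(desc))
  for (cls in c(0, 1)) {
    idx <- which(label == cls)
    n_test <- round(length(idx) * (1 - train_fraction))
    test_idx <- with_seed(seed + cls + 1L, sample(idx, n_test))
    split[test_idx] <- "test"
  }
  out <- dplyr::bind_cols(
    tibble::tibble(smiles = desc$smiles, label = label, split = split),
    desc[, setdiff(names(desc), "smiles")]
  )
  attr(out, "feature_cols") <- setdiff(names(desc), "smiles")
  attr(out, "seed") <- seed
  out
}

.feature_cols <- function(ds) {
  fc <- attr(ds, "feature_cols")
  if (is.null(fc)) setdiff(names(ds), c("smiles", "label", "split")) else fc
}

#' L1-based descriptor selection
#'
#' Ranks descriptors by the absolute coefficients of an L1-penalised
#' logistic regression fitted to the z-scored training split (hard labels)
#' and returns the top `k`. Constant (zero-variance) descriptors are
#' excluded before ranking and reported in `attr(, "dropped_constant")`.
#' Ties are broken alphabetically for determinism.
#'
#' @param ds Dataset from [build_scorer_dataset()].
#' @param k Number of descriptors to keep (default 25).
#' @param l1_c Inverse regularisation strength; the penalty is
#'   `lambda = 1 / (n * l1_c)` (default `l1_c = 1`).
#' @param seed Integer seed (the fit itself is deterministic; the seed is
#'   recorded for provenance).
#' @return Character vector of `k` descriptor names, most important first.
#' @export
select_features <- function(ds, k = 25L, l1_c = 1, seed = 1L) {
  feats <- .feature_cols(ds)
  train <- ds[ds$split == "train", , drop = FALSE]
  x <- as.matrix(train[, feats])
  sds <- apply(x, 2L, stats::sd)
  constant <- feats[sds == 0 | !is.finite(sds)]
  usable <- setdiff(feats, constant)
  stopifnot(k <= length(usable))
  xz <- scale(x[, usable, drop = FALSE])
  fit <- glmnet::glmnet(xz, train$label, family = "binomial", alpha = 1,
                        lambda = 1 / (nrow(xz) * l1_c), standardize = FALSE)
  beta <- abs(as.numeric(fit$beta))
  names(beta) <- usable
  ranked <- names(beta)[order(-beta, names(beta))]
  out <- ranked[seq_len(k)]
  attr(out, "dropped_constant") <- constant
  attr(out, "seed") <- seed
  out
}

#' Train an ion scorer
#'
#' Fits the final soft-target logistic regression: descriptors are z-scored
#' with training-split statistics, hard labels are smoothed with
#' [smooth_labels()], and the model minimises binary cross-entropy against
#' the smoothed targets (a quasi-binomial GLM with fractional responses,
#' which has the same score equations as weighted two-row duplication).
#'
#' @param ds Dataset from [build_scorer_dataset()].
#' @param features Descriptor names to use, normally from
#'   [select_features()].
#' @param alpha Label-smoothing strength (default 0.2).
#' @param threshold Decision threshold for [discretize_score()]
#'   (default 0.5).
#' @param ion_kind `"cation"` or `"anion"`, recorded in the artifact.
#' @param seed Seed recorded in the artifact (the fit is deterministic).
#' @return An object of class `"ion_scorer"`.
#' @export
train_scorer <- function(ds, features, alpha = 0.2, threshold = 0.5,
                         ion_kind = "cation", seed = 1L) {
  feats <- .feature_cols(ds)
  stopifnot(all(features %in% feats))
  train <- ds[ds$split == "train", , drop = FALSE]
  x <- as.matrix(train[, features, drop = FALSE])
  mu <- colMeans(x)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("Constant feature(s) in training split: ",
         paste(features[sds == 0], collapse = ", "), call. = FALSE)
  }
  xz <- sweep(sweep(x, 2L, mu), 2L, sds, "/")
  y_ls <- smooth_labels(train$label, alpha = alpha)
  df <- data.frame(y = y_ls, xz, check.names = FALSE)
  fit <- stats::glm(y ~ ., data = df, family = stats::quasibinomial())
  if (!fit$converged) {
    stop("Soft-target logistic regression did not converge (deviance ",
         signif(fit$deviance, 6), " after ", fit$iter, " iterations).",
         call. = FALSE)
  }
  cf <- stats::coef(fit)
  ## aliased (perfectly collinear) descriptors carry no information beyond
  ## the ones they duplicate; they get zero weight
  cf[is.na(cf)] <- 0
  structure(
    list(
      ion_kind = ion_kind,
      selected_features = features,
      standardization = list(mean = mu, sd = sds),
      intercept = unname(cf[1L]),
      weights = stats::setNames(unname(cf[-1L]), features),
      threshold = threshold,
      alpha = alpha,
      seed = seed,
      objective = "soft-target binomial cross-entropy (fractional-response GLM)",
      descriptor_set = DESCRIPTOR_SET_VERSION,
      n_train = nrow(train)
    ),
    class = "ion_scorer"
  )
}

#' @export
print.ion_scorer <- function(x, ...) {
  cat("Ion scorer (", x$ion_kind, "): ", length(x$selected_features),
      " descriptors, alpha = ", x$alpha, ", threshold = ", x$threshold,
      ", n_train = ", x$n_train, "\n", sep = "")
  invisible(x)
}

#' Score ions
#'
#' Applies a trained [train_scorer()] model: the sigmoid of the linear
#' predictor over standardized selected descriptors. Scores are invariant to
#' SMILES spelling. Unparseable or descriptor-failing ions receive `NA`
#' scores and are listed in `attr(, "failures")`.
#'
#' @param model An `"ion_scorer"`.
#' @param smiles Character vector of SMILES (or a data frame with a
#'   `smiles` column).
#' @return A tibble with columns `smiles`, `score` in `(0, 1)` and `il_like`
#'   (the thresholded 0/1 class).
#' @export
score_ions <- function(model, smiles) {
  stopifnot(inherits(model, "ion_scorer"))
  if (is.data.frame(smiles)) smiles <- smiles$smiles
  can <- ob_canonical(smiles)
  score <- rep(NA_real_, length(smiles))
  ok <- !is.na(can)
  if (any(ok)) {
    desc <- compute_descriptors(can[ok], descriptors = model$selected_features)
    x <- as.matrix(desc[, model$selected_features, drop = FALSE])
    xz <- sweep(sweep(x, 2L, model$standardization$mean),
                2L, model$standardization$sd, "/")
    eta <- drop(xz %*% model$weights) + model$intercept
    score[ok] <- stats::plogis(eta)
  }
  out <- tibble::tibble(
    smiles = smiles, score = score,
    il_like = ifelse(is.na(score), NA_integer_,
                     discretize_score(score, model$threshold))
  )
  if (any(!ok)) attr(out, "failures") <- smiles[!ok]
  out
}

#' @rdname score_ions
#' @param object An `"ion_scorer"`.
#' @param newdata SMILES character vector or data frame.
#' @param ... Unused.
#' @export
predict.ion_scorer <- function(object, newdata, ...) {
  score_ions(object, newdata)$score
}

#' Threshold an ion score
#'
#' @param score Numeric scores in `[0, 1]`.
#' @param threshold Decision threshold; a score exactly at the threshold
#'   classifies as 1 (the boundary is inclusive-positive).
#' @return Integer vector in `{0, 1}`.
#' @export
discretize_score <- function(score, threshold = 0.5) {
  stopifnot(all(score >= 0 & score <= 1, na.rm = TRUE))
  as.integer(score >= threshold)
}

#' Evaluate an ion scorer
#'
#' Accuracy and recall at the model threshold plus ROC-AUC on the continuous
#' scores, computed on the requested split.
#'
#' @param model An `"ion_scorer"`.
#' @param ds Dataset from [build_scorer_dataset()].
#' @param split Which split to evaluate (default `"test"`).
#' @return A one-row tibble with `accuracy`, `recall`, `roc_auc` and `n`.
#' @export
evaluate_scorer <- function(model, ds, split = "test") {
  eval_ds <- ds[ds$split == split, , drop = FALSE]
  stopifnot(nrow(eval_ds) > 0L)
  if (length(unique(eval_ds$label)) < 2L) {
    stop("ROC-AUC is undefined on a single-class evaluation set.",
         call. = FALSE)
  }
  scored <- score_ions(model, eval_ds$smiles)
  pred <- scored$il_like
  truth <- eval_ds$label
  acc <- mean(pred == truth)
  recall <- sum(pred == 1L & truth == 1) / sum(truth == 1)
  auc <- as.numeric(pROC::auc(pROC::roc(truth, scored$score, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  tibble::tibble(accuracy = acc, recall = recall, roc_auc = auc,
                 n = nrow(eval_ds))
}

#' @method tidy ion_scorer
#' @export
tidy.ion_scorer <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$weights)),
    estimate = c(x$intercept, unname(x$weights))
  )
}

#' @method glance ion_scorer
#' @export
glance.ion_scorer <- function(x, ...) {
  tibble::tibble(
    ion_kind = x$ion_kind, n_features = length(x$selected_features),
    alpha = x$alpha, threshold = x$threshold, n_train = x$n_train,
    descriptor_set = x$descriptor_set
  )
}

#' Persist / restore an ion scorer as JSON
#'
#' @param model An `"ion_scorer"`.
#' @param path File path.
#' @return `write_scorer()` returns `path` invisibly; `read_scorer()`
#'   returns the restored `"ion_scorer"`.
#' @export
write_scorer <- function(model, path) {
  stopifnot(inherits(model, "ion_scorer"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scorer
#' @export
read_scorer <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$selected_features <- as.character(raw$selected_features)
  raw$standardization <- list(
    mean = unlist(raw$standardization$mean),
    sd = unlist(raw$standardization$sd)
  )
  raw$weights <- unlist(raw$weights)
  structure(raw, class = "ion_scorer")
}

#' @importFrom generics tidy glance
NULL
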