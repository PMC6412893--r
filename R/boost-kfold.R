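#' Stratified k-fold plan
#'
#' Partitions sample indices into k disjoint, exhaustive validation
#' sets with class proportions preserved per fold, reproducibly under
#' `seed`. Fold assignment is delegated to [caret::createFolds()].
#'
#' @param y Class label vector.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return A `fold_plan`: list of `k` elements, each with `train` and
#'   `val` integer index vectors.
#' @export
stratified_folds <- function(y, k = 5, seed = 0) {
  if (k < 2) {
    abort("`k` must be at least 2.", class = "harsdae_config_error")
  }
  counts <- table(y)
  if (any(counts < k)) {
    abort(paste0("Cannot stratify into ", k, " folds: class(es) with fewer than ",
                 k, " samples: ", paste(names(counts)[counts < k], collapse = ", ")),
          class = "harsdae_stratify_error")
  }
  val_sets <- withr::with_seed(seed,
    caret::createFolds(factor(y), k = k, list = TRUE, returnTrain = FALSE))
  all_idx <- seq_along(y)
  plan <- lapply(val_sets, function(v) {
    list(train = setdiff(all_idx, v), val = sort(unname(v)))
  })
  names(plan) <- paste0("fold", seq_len(k))
  structure(plan, class = "fold_plan", k = k, n = length(y))
}

encode_labels <- function(y) {
  levels <- unique(as.character(y))   # first-appearance order
  list(levels = levels,
       codes = match(as.character(y), levels) - 1L)
}

#' Gradient-boosted decision-tree backend
#'
#' Multiclass gradient-boosted trees (xgboost) behind a minimal
#' hard-label interface. Class labels are encoded as contiguous
#' integers `0..M-1` in order of first appearance in `y`; predictions
#' are decoded back. Single-threaded and seeded, so refitting with the
#' same inputs reproduces the same model.
#'
#' @param X `(n, d)` numeric feature matrix.
#' @param y Length-`n` class labels (>= 2 distinct classes).
#' @param params List of backend hyperparameters: `nrounds` (boosting
#'   rounds, default 100), `max_depth`, `eta`, `seed`.
#' @return A `har_gbdt` model with a [predict()] method returning hard
#'   labels.
#' @export
fit_gbdt_backend <- function(X, y, params = list()) {
  enc <- encode_labels(y)
  if (length(enc$levels) < 2) {
    abort("Backend needs at least 2 classes.", class = "harsdae_class_error")
  }
  p <- utils::modifyList(list(nrounds = 100, max_depth = 6, eta = 0.3, seed = 0),
                         params)
  dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = enc$codes)
  booster <- xgboost::xgb.train(
    params = list(objective = "multi:softmax",
                  num_class = length(enc$levels),
                  max_depth = p$max_depth, eta = p$eta,
                  nthread = 1, seed = p$seed),
    data = dtrain, nrounds = p$nrounds, verbose = 0)
  structure(list(booster = booster, levels = enc$levels, params = p),
            class = "har_gbdt")
}

#' @export
predict.har_gbdt <- function(object, newdata, ...) {
  codes <- predict(object$booster, xgboost::xgb.DMatrix(as.matrix(newdata)))
  object$levels[codes + 1L]
}

#' Train the boosting k-fold ensemble
#'
#' The folds are processed sequentially. Fold f trains the backend on
#' its plan training indices plus one extra copy of every sample the
#' previous fold's model misclassified in its validation set (fold 1
#' gets no extras); after fold f is trained, the misjudged set is
#' replaced by fold f's own validation errors. With a perfect backend
#' this reduces exactly to plain stratified k-fold training.
#'
#' @param X `(n, d)` feature matrix.
#' @param y Length-`n` class labels.
#' @param plan A `fold_plan` from [stratified_folds()].
#' @param backend Function `(X, y) -> model` where `predict(model, X)`
#'   returns hard labels; defaults to [fit_gbdt_backend()] with
#'   `params`.
#' @param params Hyperparameters forwarded to the default backend.
#' @return A `boost_kfold` model: the k fold models, per-fold misjudged
#'   counts and training sizes, the plan, and the class encoding.
#' @export
train_boosting_kfold <- function(X, y, plan, backend = NULL,
                                 params = list()) {
  stopifnot(inherits(plan, "fold_plan"))
  X <- as.matrix(X)
  if (attr(plan, "n") != nrow(X)) {
    abort("Fold plan does not match the number of samples.",
          class = "harsdae_shape_error")
  }
  if (is.null(backend)) {
    backend <- function(X, y) fit_gbdt_backend(X, y, params)
  }
  y <- as.character(y)
  models <- vector("list", length(plan))
  misjudged_idx <- integer(0)
  misjudged_counts <- integer(length(plan))
  train_sizes <- integer(length(plan))
  for (f in seq_along(plan)) {
    tr <- plan[[f]]$train
    va <- plan[[f]]$val
    tr_x <- X[c(tr, misjudged_idx), , drop = FALSE]
    tr_y <- y[c(tr, misjudged_idx)]
    train_sizes[f] <- nrow(tr_x)
    models[[f]] <- backend(tr_x, tr_y)
    val_pred <- predict(models[[f]], X[va, , drop = FALSE])
    wrong <- va[as.character(val_pred) != y[va]]
    misjudged_idx <- wrong                      # replaced, not accumulated
    misjudged_counts[f] <- length(wrong)
  }
  structure(list(models = models, plan = plan,
                 misjudged_counts = misjudged_counts,
                 train_sizes = train_sizes,
                 levels = unique(y)),
            class = "boost_kfold")
}

#' Majority vote over the fold models
#'
#' Every fold model votes a hard label for each test sample; the modal
#' class wins. Ties break toward the smallest class index in the
#' model's contiguous `0..M-1` first-appearance encoding (bincount
#' argmax semantics).
#'
#' @param model A `boost_kfold` model.
#' @param newdata `(n, d)` feature matrix.
#' @return Length-`n` predicted label vector.
#' @export
predict_majority_vote <- function(model, newdata) {
  newdata <- as.matrix(newdata)
  votes <- vapply(model$models, function(m) {
    match(as.character(predict(m, newdata)), model$levels) - 1L
  }, integer(nrow(newdata)))
  votes <- matrix(votes, nrow = nrow(newdata))
  winners <- apply(votes, 1, function(v) {
    counts <- tabulate(v + 1L, nbins = length(model$levels))
    which.max(counts) - 1L    # which.max takes the first (smallest) index on ties
  })
  model$levels[winners + 1L]
}

#' @export
predict.boost_kfold <- function(object, newdata, ...) {
  predict_majority_vote(object, newdata)
}

#' Fit the boosting k-fold classifier on extracted features
#'
#' Convenience wrapper around [stratified_folds()] and
#' [train_boosting_kfold()] for a `har_features` table.
#'
#' @param features A `har_features` tibble (from
#'   [features_from_windows()]).
#' @param k Fold count.
#' @param seed Seed for the fold plan.
#' @param params Backend hyperparameters (see [fit_gbdt_backend()]).
#' @return A `boost_kfold` model.
#' @examples
#' \donttest{
#' ds <- simulate_har_dataset(duration = 3, recordings_per_class = 10, seed = 1)
#' w <- windows_from_recordings(ds, schema_imu(50), 64, 64)
#' sc <- fit_minmax(w)
#' ws <- apply_minmax(w, sc)
#' st <- fit_sdae(ws, sdae_config(c(20, 8), pretrain_epochs = 2,
#'                                fine_tune_epochs = 2))
#' fe <- features_from_windows(ws, st)
#' fit <- boost_kfold(fe, k = 5, seed = 0, params = list(nrounds = 20))
#' }
#' @export
boost_kfold <- function(features, k = 5, seed = 0, params = list()) {
  plan <- stratified_folds(features$activity, k = k, seed = seed)
  train_boosting_kfold(features$features, features$activity, plan,
                       params = params)
}
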