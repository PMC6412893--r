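test_that("stratified folds are disjoint, exhaustive, balanced and seeded", {
  y <- rep(c("a", "b"), each = 10)
  plan <- stratified_folds(y, k = 5, seed = 1)
  vals <- lapply(plan, `[[`, "val")
  expect_setequal(unlist(vals), seq_along(y))
  expect_equal(sum(lengths(vals)), length(y))        # disjoint + exhaustive
  for (f in plan) {
    expect_equal(as.integer(table(y[f$val])), c(2L, 2L))
    expect_setequal(c(f$train, f$val), seq_along(y))
  }
  expect_identical(stratified_folds(y, 5, seed = 1), plan)
  expect_error(stratified_folds(c("a", rep("b", 10)), k = 5),
               class = "harsdae_stratify_error")
  expect_error(stratified_folds(y, k = 1), class = "harsdae_config_error")
})

test_that("gbdt backend separates blobs, predicts known labels, and is deterministic", {
  blobs <- toy_features(25, means = list(lo = c(0, 0), hi = c(5, 5)))
  fit <- fit_gbdt_backend(blobs$features, blobs$activity, list(nrounds = 20))
  pred <- predict(fit, blobs$features)
  expect_equal(pred, blobs$activity)                 # training accuracy 1.0
  expect_true(all(pred %in% unique(blobs$activity)))
  fit2 <- fit_gbdt_backend(blobs$features, blobs$activity, list(nrounds = 20))
  expect_identical(predict(fit2, blobs$features), pred)
  expect_error(fit_gbdt_backend(blobs$features, rep("one", nrow(blobs))),
               class = "harsdae_class_error")
})

test_that("a perfect backend reduces boosting k-fold to plain stratified k-fold", {
  y <- rep(c("a", "b", "c"), each = 10)
  plan <- stratified_folds(y, k = 5, seed = 2)
  model <- train_boosting_kfold(id_features(30), y, plan,
                                backend = oracle_backend(y))
  expect_equal(model$misjudged_counts, rep(0L, 5))
  base_sizes <- vapply(plan, function(f) length(f$train), integer(1))
  expect_equal(model$train_sizes, unname(base_sizes))  # fold-by-fold equality
})

test_that("misjudged validation samples are duplicated into the next fold only", {
  y <- rep(c("a", "b"), each = 15)
  plan <- stratified_folds(y, k = 3, seed = 3)
  m <- 4
  wrong_ids <- plan[[1]]$val[seq_len(m)]
  model <- train_boosting_kfold(id_features(30), y, plan,
                                backend = erring_backend(y, wrong_ids,
                                                         unique(y)))
  base_sizes <- unname(vapply(plan, function(f) length(f$train), integer(1)))
  expect_equal(model$train_sizes[1], base_sizes[1])
  expect_equal(model$train_sizes[2], base_sizes[2] + m)
  # wrong_ids not in fold 3's validation set -> replaced, not accumulated
  expect_equal(model$misjudged_counts[2], sum(wrong_ids %in% plan[[2]]$val))
  expect_equal(model$train_sizes[3],
               base_sizes[3] + model$misjudged_counts[2])
  expect_error(train_boosting_kfold(id_features(10), y[1:10],
                                    structure(list(), class = "fold_plan", n = 5)),
               class = "harsdae_shape_error")
})

test_that("majority vote follows bincount-argmax semantics incl. tie-break", {
  mk_model <- function(votes_matrix, levels) {
    # k stub models each returning a fixed vote column
    models <- lapply(seq_len(ncol(votes_matrix)), function(j) {
      structure(list(v = levels[votes_matrix[, j] + 1L]), class = "stub_const")
    })
    structure(list(models = models, levels = levels), class = "boost_kfold")
  }
  registerS3method("predict", "stub_const", function(object, newdata, ...) {
    rep_len(object$v, nrow(newdata))
  })
  levels3 <- c("c0", "c1", "c2")
  x1 <- matrix(0, 1, 1)
  expect_equal(predict_majority_vote(mk_model(matrix(rep(2, 5), 1), levels3), x1),
               "c2")
  expect_equal(predict_majority_vote(mk_model(matrix(c(2, 2, 1, 1, 0), 1), levels3), x1),
               "c1")   # 2-2 tie between c1 and c2: smaller index wins
  expect_equal(predict_majority_vote(mk_model(matrix(c(0, 0, 0, 1, 2), 1), levels3), x1),
               "c0")
  # exhaustive: all 3-class patterns of 5 votes vs a bincount-argmax oracle
  grid <- as.matrix(expand.grid(rep(list(0:2), 5)))
  got <- apply(grid, 1, function(v) {
    predict_majority_vote(mk_model(matrix(v, 1), levels3), x1)
  })
  want <- apply(grid, 1, function(v) {
    levels3[which.max(tabulate(v + 1L, 3))]
  })
  expect_equal(got, want)
  # permutation invariance away from the tie-break
  v <- c(0, 1, 1, 1, 2)
  for (i in 1:5) {
    perm <- sample(v)
    expect_equal(predict_majority_vote(mk_model(matrix(perm, 1), levels3), x1), "c1")
  }
})

test_that("boost_kfold fits features end to end and tidies", {
  blobs <- toy_features(20, means = list(a = c(0, 0), b = c(4, 4), c = c(-4, 4)),
                        sd = 0.5)
  fit <- boost_kfold(blobs, k = 5, seed = 0, params = list(nrounds = 20))
  td <- tidy(fit)
  expect_equal(nrow(td), 5)
  expect_equal(td$train_size,
               unname(vapply(fit$plan, function(f) length(f$train), integer(1))) +
                 c(0L, head(td$misjudged, -1)))
  pred <- predict(fit, blobs$features)
  expect_gt(mean(pred == blobs$activity), 0.9)
  expect_equal(glance(fit)$k, 5)
})
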