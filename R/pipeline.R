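#' End-to-end activity-recognition pipeline
#'
#' Runs the full method on a nested recording tibble: sliding-window
#' segmentation and flattening, a stratified train/test split, min-max
#' standardisation with training extrema, one stacked denoising
#' autoencoder per sensor, cross-sensor feature concatenation, the
#' boosting k-fold gradient-boosted-tree ensemble, majority-vote
#' prediction on the held-out test windows, and the scatter-trace
#' separability report comparing raw standardised samples with the
#' extracted features.
#'
#' @param dataset Nested recording tibble (`recording_id`, `activity`,
#'   `signals`), e.g. from [simulate_har_dataset()].
#' @param schema Sensor schema tibble.
#' @param window_len,stride Sliding-window size and step, in samples.
#' @param sdae An [sdae_config()] (or named per-sensor list).
#' @param k Fold count of the boosting k-fold ensemble.
#' @param test_fraction Held-out fraction of windows.
#' @param gbdt_params Backend hyperparameters (see
#'   [fit_gbdt_backend()]).
#' @param seed Integer seed driving the split, SDAE training and folds.
#' @return A `har_pipeline_fit` list: `eval` (test-set [macro_prf()]
#'   report), `model` (the `boost_kfold`), `stacks`, `scaler`,
#'   `divergence` (training-set [divergence_report()]), `features`
#'   (train/test `har_features`), and `windows` (the split).
#' @export
har_pipeline <- function(dataset, schema = schema_imu(50),
                         window_len = 128, stride = window_len,
                         sdae = sdae_config(c(100, 30)),
                         k = 5, test_fraction = 0.3,
                         gbdt_params = list(), seed = 0) {
  windows <- windows_from_recordings(dataset, schema, window_len, stride)
  split <- split_train_test(windows, test_fraction, seed = seed)
  scaler <- fit_minmax(split$train)
  train_s <- apply_minmax(split$train, scaler)
  test_s <- apply_minmax(split$test, scaler)
  if (inherits(sdae, "sdae_config")) sdae$seed <- sdae$seed + seed
  stacks <- fit_sdae(train_s, sdae)
  feats_train <- features_from_windows(train_s, stacks)
  feats_test <- features_from_windows(test_s, stacks)
  model <- boost_kfold(feats_train, k = k, seed = seed, params = gbdt_params)
  pred <- predict_majority_vote(model, feats_test$features)
  eval <- evaluate_predictions(feats_test$activity, pred,
                               class_order = sort(unique(windows$activity)))
  raw_train <- do.call(cbind, lapply(sensor_names(train_s),
                                     function(s) train_s[[s]]))
  divergence <- divergence_report(raw_train, feats_train$features,
                                  feats_train$activity)
  structure(list(eval = eval, model = model, stacks = stacks,
                 scaler = scaler, divergence = divergence,
                 features = list(train = feats_train, test = feats_test),
                 windows = split),
            class = "har_pipeline_fit")
}

#' @export
print.har_pipeline_fit <- function(x, ...) {
  cat("Activity-recognition pipeline fit\n")
  print(x$eval)
  print(x$divergence$totals)
  invisible(x)
}

#' Export a feature table as CSV
#'
#' Writes the `features` matrix-column with its column names plus the
#' window metadata, one row per window — the package's plain-text
#' interchange format for learned or hand-crafted features.
#'
#' @param features A `har_features` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  f <- features$features
  if (is.null(colnames(f))) colnames(f) <- paste0("f", seq_len(ncol(f)))
  keep <- intersect(c("window_id", "recording_id", "activity"), names(features))
  readr::write_csv(dplyr::bind_cols(features[keep], tibble::as_tibble(f)),
                   path, progress = FALSE)
  invisible(path)
}
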