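test_that("gravity decomposition projects onto the window-mean direction", {
  w <- matrix(rep(c(0, 0, 9.8), each = 16), 16)
  gd <- gravity_decompose(w)
  expect_equal(gd$vertical, rep(9.8, 16))
  expect_equal(gd$horizontal, rep(0, 16), tolerance = 1e-9)
  gd2 <- gravity_decompose(matrix(rep(c(3, 4, 0), each = 8), 8))
  expect_equal(gd2$vertical, rep(5, 8))
  expect_equal(gd2$horizontal, rep(0, 8), tolerance = 1e-9)
  # oscillation orthogonal to gravity stays in the horizontal channel
  t <- (0:63) / 64                # exactly 4 full periods: zero mean
  osc <- sin(2 * pi * 4 * t)
  w3 <- cbind(osc, 0, 9.8)
  gd3 <- gravity_decompose(w3)
  expect_lt(diff(range(gd3$vertical)), 0.05)
  expect_equal(gd3$horizontal, abs(osc), tolerance = 1e-6)
  expect_warning(gravity_decompose(matrix(0, 8, 3)), "z-axis")
})

test_that("summary statistics follow population conventions", {
  s <- harsdae:::basic_stats(c(1, 2, 3), "p_")
  expect_equal(unname(s[c("p_mean", "p_range")]), c(2, 2))
  expect_equal(unname(s["p_sd"]), sqrt(2 / 3))      # population sd ~ 0.8165
  expect_equal(unname(s["p_var"]), 2 / 3)
  expect_equal(unname(s[c("p_q1", "p_q2", "p_q3")]), c(1.5, 2, 2.5))
})

test_that("hand-crafted features cover every cluster with a stable layout", {
  schema <- schema_imu_baro(50)
  win <- withr::with_seed(9, list(
    acc = matrix(rnorm(128 * 3, mean = c(0, 0, 9.8)), 128, 3, byrow = TRUE),
    gyro = matrix(rnorm(128 * 3, sd = 0.3), 128, 3),
    mag = matrix(rnorm(128 * 3, mean = c(30, 10, -20)), 128, 3, byrow = TRUE),
    baro = matrix(101325 - 2 * (1:128) / 50, 128, 1)))
  f <- extract_handcrafted_features(win, schema)
  # 2 gravity clusters x 10 + 3 sensors x (23 modulus + 3 correlations) + 2x2 pressure
  expect_length(f, 2 * 10 + 3 * 26 + 4)
  expect_true(all(is.finite(f)))
  expect_identical(f, extract_handcrafted_features(win, schema))
  # identical axes -> unit correlation
  win2 <- win
  win2$acc[, 2] <- win2$acc[, 1]
  expect_equal(unname(extract_handcrafted_features(win2, schema)["acc_cor_xy"]), 1)
  # modulus of a constant (3,4,0) signal is constant 5 with zero variance
  win3 <- win
  win3$acc <- matrix(rep(c(3, 4, 0), each = 128), 128)
  f3 <- extract_handcrafted_features(win3, schema)
  expect_equal(unname(f3["acc_mod_mean"]), 5)
  expect_equal(unname(f3["acc_mod_var"]), 0)
  # missing sensor -> cluster omitted with a warning
  expect_warning(f4 <- extract_handcrafted_features(win[c("acc", "gyro", "baro")],
                                                    schema), "mag")
  expect_false(any(startsWith(names(f4), "mag_")))
  expect_error(extract_handcrafted_features(lapply(win, function(m) m[1:4, , drop = FALSE]),
                                            schema),
               class = "harsdae_config_error")
})

test_that("pressure change features honour the 6 s / 10 s buffer spans", {
  schema <- schema_imu_baro(50)
  buf <- 101325 - 12 * seq(0, 10, by = 1 / 50)    # -12 Pa/s over 10 s
  win <- list(acc = matrix(9.8, 128, 3), gyro = matrix(0, 128, 3),
              mag = matrix(1, 128, 3), baro = matrix(buf[1:128], 128, 1))
  f <- suppressWarnings(extract_handcrafted_features(win, schema,
                                                     pressure_buffer = buf))
  expect_equal(unname(f["baro_10s_change"]), -120, tolerance = 0.5)
  expect_equal(unname(f["baro_6s_change"]), -72, tolerance = 0.5)
})

test_that("handcrafted feature table feeds the gbdt backend", {
  ds <- tiny_dataset()
  w <- windows_from_recordings(ds, schema_imu(50), 64, 64)
  hf <- handcrafted_features(w)
  expect_s3_class(hf, "har_features")
  expect_equal(nrow(hf), nrow(w))
  expect_true(all(is.finite(hf$features)))
  fit <- fit_gbdt_backend(hf$features, hf$activity, list(nrounds = 30))
  acc <- mean(predict(fit, hf$features) == hf$activity)
  expect_gt(acc, 0.95)    # engineered features separate the synthetic classes
})

test_that("softmax head outputs a probability simplex and learns separable data", {
  ds <- tiny_dataset(seed = 3, recordings_per_class = 6)
  w <- windows_from_recordings(ds, schema_imu(50), 64, 64)
  ws <- apply_minmax(w, fit_minmax(w))
  cfg <- sdae_config(c(16, 8), pretrain_epochs = 3, fine_tune_epochs = 0, seed = 1)
  stacks <- fit_sdae(ws, cfg)
  clf0 <- train_single_sdae_classifier(stacks, ws, epochs = 0, seed = 2)
  p0 <- predict_proba(clf0, ws)
  expect_equal(unname(rowSums(p0)), rep(1, nrow(ws)), tolerance = 1e-9)
  expect_true(all(p0 > 0 & p0 < 1))
  expect_true(all(predict(clf0, ws) %in% unique(ws$activity)))
  clf <- train_single_sdae_classifier(stacks, ws, epochs = 200,
                                      learning_rate = 0.1, seed = 2)
  acc <- mean(predict(clf, ws) == ws$activity)
  expect_gt(acc, 0.9)
  expect_lt(tail(clf$loss_history, 1), clf$loss_history[1])
})

test_that("full pipeline and both baselines run on shared data and seeds", {
  ds <- tiny_dataset(seed = 11, recordings_per_class = 6)
  fit <- suppressWarnings(
    har_pipeline(ds, schema_imu(50), window_len = 64, stride = 64,
                 sdae = sdae_config(c(16, 8), pretrain_epochs = 3,
                                    fine_tune_epochs = 2),
                 k = 3, gbdt_params = list(nrounds = 30), seed = 1))
  expect_s3_class(fit$eval, "har_eval")
  expect_true(fit$eval$accuracy >= 0 && fit$eval$accuracy <= 1)
  # baseline (a): single SDAE + softmax on the same standardised windows
  train_s <- apply_minmax(fit$windows$train, fit$scaler)
  test_s <- apply_minmax(fit$windows$test, fit$scaler)
  clf <- train_single_sdae_classifier(fit$stacks, train_s, epochs = 5, seed = 1)
  ev_a <- suppressWarnings(evaluate_predictions(test_s$activity, predict(clf, test_s)))
  expect_s3_class(ev_a, "har_eval")
  # baseline (b): hand-crafted features + gbdt
  hf_tr <- handcrafted_features(fit$windows$train)
  hf_te <- handcrafted_features(fit$windows$test)
  gb <- fit_gbdt_backend(hf_tr$features, hf_tr$activity, list(nrounds = 30))
  ev_b <- suppressWarnings(evaluate_predictions(hf_te$activity,
                                                predict(gb, hf_te$features)))
  expect_s3_class(ev_b, "har_eval")
})
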