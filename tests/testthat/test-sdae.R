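test_that("corruption is identity at rate 0, total at rate 1, Bernoulli between", {
  x <- 1:10 + 0.5
  expect_identical(corrupt_input(x, 0), x)
  expect_equal(withr::with_seed(1, corrupt_input(x, 1)), rep(0, 10))
  n <- 10000
  zeros <- withr::with_seed(1, sum(corrupt_input(rep(1, n), 0.4) == 0))
  # 99% binomial interval around n * 0.4
  band <- qbinom(c(0.005, 0.995), n, 0.4)
  expect_gte(zeros, band[1])
  expect_lte(zeros, band[2])
  expect_error(corrupt_input(x, 1.5), class = "harsdae_config_error")
})

test_that("encode/decode layers are sigmoid affine maps with shape contracts", {
  p <- list(W_enc = matrix(0, 4, 2), b_enc = c(0, 0),
            W_dec = matrix(0, 2, 4), b_dec = rep(0, 4))
  expect_equal(encode_layer(rep(1, 4), p), rep(0.5, 2))
  expect_equal(decode_layer(c(1, 1), p), rep(0.5, 4))
  p1 <- list(W_enc = matrix(1), b_enc = 0, W_dec = matrix(1), b_dec = 0)
  expect_equal(encode_layer(log(3), p1), 0.75)
  expect_error(encode_layer(rep(1, 3), p), class = "harsdae_shape_error")
  expect_error(decode_layer(rep(1, 3), p), class = "harsdae_shape_error")
  # outputs strictly inside (0,1)
  withr::with_seed(2, {
    pr <- harsdae:::init_layer_params(6, 3)
    h <- encode_layer(matrix(rnorm(60), 10), pr)
    r <- decode_layer(h, pr)
    expect_true(all(h > 0 & h < 1))
    expect_true(all(r > 0 & r < 1))
  })
})

test_that("pretraining reduces reconstruction error below random init", {
  # data on a 2-d linear manifold embedded in 10-d
  deltas <- withr::with_seed(3, {
    sapply(1:3, function(s) {
      z <- matrix(runif(200 * 2), 200, 2)
      A <- matrix(runif(2 * 10, -1, 1), 2, 10)
      x <- harsdae:::sigmoid(z %*% A)
      cfg0 <- sdae_config(2, dropout = 0, pretrain_epochs = 0, seed = s)
      cfg <- sdae_config(2, dropout = 0, pretrain_epochs = 40,
                         learning_rate = 5e-3, seed = s)
      init <- pretrain_layer(x, cfg0, 1)
      trained <- pretrain_layer(x, cfg, 1)
      harsdae:::dae_loss(x, init) - harsdae:::dae_loss(x, trained)
    })
  })
  expect_true(mean(deltas) > 0)
  expect_true(all(deltas > 0))
})

test_that("zero-epoch pretraining returns the initialisation and history tracks epochs", {
  x <- withr::with_seed(4, matrix(runif(50 * 6), 50, 6))
  cfg0 <- sdae_config(3, pretrain_epochs = 0, seed = 9)
  p0 <- pretrain_layer(x, cfg0, 1)
  ref <- withr::with_seed(cfg0$seed + 1L, harsdae:::init_layer_params(6, 3))
  expect_equal(p0$W_enc, ref$W_enc)
  expect_length(attr(p0, "loss_history"), 0)
  cfg2 <- sdae_config(3, pretrain_epochs = 2, batch_size = 32, seed = 9)
  expect_length(attr(pretrain_layer(x, cfg2, 1), "loss_history"), 2)
})

test_that("greedy stacking chains layer widths and concatenation sums them", {
  x <- withr::with_seed(5, matrix(runif(60 * 384), 60, 384))
  cfg <- sdae_config(c(100, 30), pretrain_epochs = 1, fine_tune_epochs = 0, seed = 0)
  st <- build_stack(x, cfg)
  expect_length(st$layers, 2)
  expect_equal(dim(st$layers[[1]]$W_enc), c(384, 100))
  expect_equal(dim(st$layers[[2]]$W_enc), c(100, 30))   # layer 2 input = layer 1 width
  f <- extract_features(st, x)
  expect_equal(ncol(f), 30)
  expect_true(all(is.finite(f)) && all(f > 0 & f < 1))
  # three such sensors concatenate to 90 learned features
  cat3 <- concat_sensor_features(list(a = f, b = f, c = f))
  expect_equal(ncol(cat3), 90)
  expect_error(concat_sensor_features(list(a = f, b = f[-1, ])),
               class = "harsdae_alignment_error")
  expect_error(sdae_config(integer(0)), class = "harsdae_config_error")
})

test_that("single-layer stack and a three-layer config build as specified", {
  x <- withr::with_seed(6, matrix(runif(40 * 50), 40, 50))
  st1 <- build_stack(x, sdae_config(8, pretrain_epochs = 1, seed = 1))
  expect_length(st1$layers, 1)
  st3 <- build_stack(x, sdae_config(c(30, 15, 5), pretrain_epochs = 1, seed = 1))
  expect_equal(ncol(extract_features(st3, x)), 5)
})

test_that("unsupervised fine-tuning does not worsen the unrolled reconstruction", {
  x <- withr::with_seed(7, {
    z <- matrix(runif(150 * 2), 150, 2)
    harsdae:::sigmoid(z %*% matrix(runif(2 * 12, -1, 1), 2, 12))
  })
  cfg <- sdae_config(c(6, 3), dropout = 0.1, pretrain_epochs = 10,
                     fine_tune_epochs = 10, learning_rate = 5e-3, seed = 2)
  st <- build_stack(x, cfg)
  before <- reconstruction_mse(st, x)
  st_ft <- fine_tune_stack(st, x)
  expect_lte(reconstruction_mse(st_ft, x), before + 1e-6)
  # zero fine-tune epochs leave parameters untouched
  cfg0 <- cfg
  cfg0$fine_tune_epochs <- 0L
  expect_equal(fine_tune_stack(st, x, cfg0)$layers, st$layers)
  # shapes survive fine-tuning
  expect_equal(dim(st_ft$layers[[1]]$W_enc), dim(st$layers[[1]]$W_enc))
})

test_that("feature extraction is deterministic and corruption-free", {
  x <- withr::with_seed(8, matrix(runif(30 * 20), 30, 20))
  st <- build_stack(x, sdae_config(5, pretrain_epochs = 2, seed = 3))
  expect_identical(extract_features(st, x), extract_features(st, x))
  expect_error(extract_features(structure(list(layers = list()), class = "sdae"), x),
               class = "harsdae_config_error")
})
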