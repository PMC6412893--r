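#' Single-SDAE classifier: softmax head over the encoder network
#'
#' Baseline in which the pretrained per-sensor encoders feed a softmax
#' output layer directly, trained by gradient descent on the
#' categorical cross-entropy; gradients flow into the encoding network
#' as well (joint fine-tuning) unless `fine_tune_encoder = FALSE`.
#'
#' @param stacks An `sdae_set` of pretrained per-sensor stacks.
#' @param windows Standardised training `har_windows` tibble.
#' @param epochs Gradient-descent epochs over the training set (0 keeps
#'   the randomly initialised head).
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size.
#' @param fine_tune_encoder Whether encoder weights are updated jointly
#'   with the head.
#' @param seed Integer seed.
#' @return A `single_sdae` classifier with [predict()] (hard labels)
#'   and [predict_proba()] methods.
#' @export
train_single_sdae_classifier <- function(stacks, windows, epochs = 20,
                                         learning_rate = 1e-2,
                                         batch_size = 32,
                                         fine_tune_encoder = TRUE,
                                         seed = 0) {
  stopifnot(inherits(stacks, "sdae_set"))
  sensors <- names(stacks)
  enc <- encode_labels(windows$activity)
  M <- length(enc$levels)
  widths <- vapply(stacks, function(s) {
    ncol(s$layers[[length(s$layers)]]$W_enc)
  }, integer(1))
  F_dim <- sum(widths)
  withr::with_seed(seed, {
    lim <- sqrt(6 / (F_dim + M))
    W <- matrix(runif(F_dim * M, -lim, lim), F_dim, M)
    b <- numeric(M)
    head_state <- adam_state(list(W = W, b = b))
    n <- nrow(windows)
    onehot <- diag(M)[enc$codes + 1L, , drop = FALSE]
    history <- numeric(0)
    for (epoch in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (b_start in seq(1, n, by = batch_size)) {
        idx <- ord[b_start:min(b_start + batch_size - 1, n)]
        # forward through every sensor's encoder chain, keeping activations
        acts <- lapply(sensors, function(s) {
          a <- list(windows[[s]][idx, , drop = FALSE])
          for (p in stacks[[s]]$layers) a <- c(a, list(encode_layer(a[[length(a)]], p)))
          a
        })
        names(acts) <- sensors
        feats <- do.call(cbind, lapply(acts, function(a) a[[length(a)]]))
        logits <- sweep(feats %*% W, 2, b, "+")
        logits <- logits - apply(logits, 1, max)
        p_hat <- exp(logits) / rowSums(exp(logits))
        yb <- onehot[idx, , drop = FALSE]
        loss <- -mean(rowSums(yb * log(pmax(p_hat, 1e-12))))
        if (!is.finite(loss)) {
          abort("Non-finite classification loss (training diverged).",
                class = "harsdae_divergence_error")
        }
        losses <- c(losses, loss)
        delta <- (p_hat - yb) / length(idx)
        gW <- t(feats) %*% delta
        gb <- colSums(delta)
        upd <- adam_update(list(W = W, b = b), list(W = gW, b = gb),
                           head_state, learning_rate)
        if (fine_tune_encoder) {
          dfeats <- delta %*% t(W)
          off <- 0L
          for (s in sensors) {
            ds <- dfeats[, off + seq_len(widths[[s]]), drop = FALSE]
            off <- off + widths[[s]]
            layers <- stacks[[s]]$layers
            a <- acts[[s]]
            for (l in rev(seq_along(layers))) {
              dz <- ds * a[[l + 1]] * (1 - a[[l + 1]])
              gWe <- t(a[[l]]) %*% dz
              gbe <- colSums(dz)
              ds <- dz %*% t(layers[[l]]$W_enc)
              layers[[l]]$W_enc <- layers[[l]]$W_enc - learning_rate * gWe
              layers[[l]]$b_enc <- layers[[l]]$b_enc - learning_rate * gbe
            }
            stacks[[s]]$layers <- layers
          }
        }
        W <- upd$params$W
        b <- upd$params$b
        head_state <- upd$state
      }
      history <- c(history, mean(losses))
    }
    structure(list(stacks = stacks, W = W, b = b, levels = enc$levels,
                   loss_history = history),
              class = "single_sdae")
  })
}

single_sdae_features <- function(object, windows) {
  do.call(cbind, lapply(names(object$stacks), function(s) {
    extract_features(object$stacks[[s]], windows[[s]])
  }))
}

#' Class probabilities from a single-SDAE classifier
#'
#' @param object A `single_sdae` model.
#' @param windows Standardised `har_windows` tibble.
#' @return `(n, M)` matrix of softmax probabilities (rows sum to 1),
#'   columns named by class.
#' @export
predict_proba <- function(object, windows) {
  feats <- single_sdae_features(object, windows)
  logits <- sweep(feats %*% object$W, 2, object$b, "+")
  logits <- logits - apply(logits, 1, max)
  p <- exp(logits) / rowSums(exp(logits))
  colnames(p) <- object$levels
  p
}

#' @export
predict.single_sdae <- function(object, newdata, ...) {
  p <- predict_proba(object, newdata)
  object$levels[max.col(p, ties.method = "first")]
}

#' Decompose an accelerometer window into vertical and horizontal parts
#'
#' The gravity direction is estimated as the unit vector of the
#' window-mean acceleration; the vertical component is the signed
#' projection of each sample onto it and the horizontal component is
#' the magnitude of the residual. When the mean vector is near zero the
#' device z-axis is used with a warning.
#'
#' @param acc_window `(w, 3)` accelerometer window in m/s^2.
#' @return List with numeric series `vertical` and `horizontal`.
#' @examples
#' gravity_decompose(matrix(rep(c(3, 4, 0), each = 4), 4))
#' @export
gravity_decompose <- function(acc_window) {
  acc_window <- as.matrix(acc_window)
  stopifnot(ncol(acc_window) == 3)
  g <- colMeans(acc_window)
  nrm <- sqrt(sum(g^2))
  if (nrm < 1e-8) {
    warn("Window-mean acceleration is near zero; falling back to the device z-axis.")
    u <- c(0, 0, 1)
  } else {
    u <- g / nrm
  }
  vertical <- drop(acc_window %*% u)
  resid <- acc_window - tcrossprod(vertical, u)
  list(vertical = vertical, horizontal = sqrt(rowSums(resid^2)))
}

basic_stats <- function(x, prefix) {
  n <- length(x)
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)   # linear interpolation
  v <- c(mean(x), var(x) * (n - 1) / n, sd(x) * sqrt((n - 1) / n),
         median(x), min(x), max(x), max(x) - min(x), q)
  names(v) <- paste0(prefix, c("mean", "var", "sd", "median", "min", "max",
                               "range", "q1", "q2", "q3"))
  v
}

lag1_autocorr <- function(x) {
  if (sd(x) == 0) return(0)
  n <- length(x)
  cor(x[-1], x[-n])
}

modulus_stats <- function(x, dt, prefix) {
  n <- length(x)
  ac <- lag1_autocorr(x)
  kur <- if (sd(x) == 0) 0 else e1071::kurtosis(x, type = 1)
  ske <- if (sd(x) == 0) 0 else e1071::skewness(x, type = 1)
  integ <- pracma::trapz(seq(0, by = dt, length.out = n), x)
  dbl <- pracma::trapz(seq(0, by = dt, length.out = n),
                       pracma::cumtrapz(seq(0, by = dt, length.out = n), x))
  fft_mag <- Mod(fft(x))[2:8]   # 7 lowest non-DC coefficients
  v <- c(basic_stats(x, ""), kurtosis = kur, skewness = ske,
         rms = sqrt(mean(x^2)), integral = integ, double_integral = dbl,
         autocorr = ac,
         stats::setNames(fft_mag, paste0("fft", 1:7)))
  names(v) <- paste0(prefix, names(v))
  v
}

axis_correlations <- function(mat, prefix) {
  cc <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) return(0)
    cor(a, b)
  }
  stats::setNames(c(cc(mat[, 1], mat[, 2]), cc(mat[, 1], mat[, 3]),
                    cc(mat[, 2], mat[, 3])),
                  paste0(prefix, c("cor_xy", "cor_xz", "cor_yz")))
}

pressure_stats <- function(p, rate, span_s, prefix) {
  n_span <- min(length(p), max(2L, as.integer(round(span_s * rate))))
  sub <- p[(length(p) - n_span + 1):length(p)]
  stats::setNames(c(sub[length(sub)] - sub[1],
                    sd(sub) * sqrt((length(sub) - 1) / length(sub))),
                  paste0(prefix, c("change", "sd")))
}

#' Hand-crafted feature vector for one multi-sensor window
#'
#' The engineered feature set used by the boosted-tree baseline:
#' summary statistics (mean, population variance and standard
#' deviation, median, min, max, range, quartiles Q1-Q3) of the vertical
#' and horizontal accelerometer components; for each of accelerometer,
#' gyroscope and magnetometer the same statistics of the per-sample
#' modulus series plus kurtosis, skewness, RMS, trapezoidal integral
#' and double integral, lag-1 autocorrelation and the magnitudes of the
#' 7 lowest non-DC Fourier coefficients; pairwise Pearson correlations
#' between the three axes of each sensor; and, when a barometer is
#' present, the change value (last minus first sample) and standard
#' deviation of the pressure over 6 s and 10 s spans taken from the end
#' of the supplied pressure buffer.
#'
#' @param window Named list of `(w, d_k)` sensor matrices (e.g. one
#'   element of [segment_windows()] output sliced to a window), window
#'   length >= 8.
#' @param schema Sensor schema tibble.
#' @param pressure_buffer Optional pressure series longer than the
#'   window, so the 6 s / 10 s spans can exceed the classification
#'   window; defaults to the window's own pressure channel.
#' @return Named numeric feature vector with a fixed, documented order.
#' @export
extract_handcrafted_features <- function(window, schema,
                                         pressure_buffer = NULL) {
  check_schema(schema)
  w <- nrow(window[[1]])
  if (w < 8) {
    abort("Hand-crafted features need windows of at least 8 samples.",
          class = "harsdae_config_error")
  }
  rate <- schema$sampling_rate[1]
  dt <- 1 / rate
  feats <- numeric(0)
  if ("acc" %in% names(window)) {
    gd <- gravity_decompose(window$acc)
    feats <- c(feats, basic_stats(gd$vertical, "acc_vert_"),
               basic_stats(gd$horizontal, "acc_horiz_"))
  }
  for (s in intersect(c("acc", "gyro", "mag"), names(window))) {
    mat <- window[[s]]
    modulus <- sqrt(rowSums(mat^2))
    feats <- c(feats, modulus_stats(modulus, dt, paste0(s, "_mod_")),
               axis_correlations(mat, paste0(s, "_")))
  }
  missing <- setdiff(schema$name, names(window))
  if (length(missing) > 0) {
    warn(paste0("Sensor(s) absent from window; feature cluster(s) omitted: ",
                paste(missing, collapse = ", ")))
  }
  if ("baro" %in% names(window)) {
    p <- pressure_buffer %||% window$baro[, 1]
    feats <- c(feats, pressure_stats(p, rate, 6, "baro_6s_"),
               pressure_stats(p, rate, 10, "baro_10s_"))
  }
  feats
}

#' Hand-crafted features for every window of a sample table
#'
#' Applies [extract_handcrafted_features()] to each row of a
#' `har_windows` tibble (using the stored window length to restore the
#' per-sensor `(w, d)` layout). Use *unstandardised* windows here: the
#' features are defined in native sensor units.
#'
#' @param windows A `har_windows` tibble.
#' @param schema Sensor schema tibble (defaults to the schema the
#'   windows were cut with).
#' @return A `har_features` tibble (`window_id`, `recording_id`,
#'   `activity`, `features` matrix-column with named columns).
#' @export
handcrafted_features <- function(windows, schema = attr(windows, "schema")) {
  check_schema(schema)
  w_len <- attr(windows, "window_len")
  sensors <- intersect(schema$name, sensor_names(windows))
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    win <- lapply(stats::setNames(nm = sensors), function(s) {
      n_ax <- schema$n_axes[schema$name == s]
      matrix(windows[[s]][i, ], w_len, n_ax, byrow = TRUE)
    })
    extract_handcrafted_features(win, schema[schema$name %in% sensors, ])
  })
  feats <- do.call(rbind, rows)
  keep <- intersect(c("window_id", "recording_id", "activity"), names(windows))
  out <- tibble::as_tibble(windows[keep])
  out$features <- feats
  class(out) <- c("har_features", class(out))
  out
}
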