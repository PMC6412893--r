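#' Configuration of one per-sensor stacked denoising autoencoder
#'
#' One denoising autoencoder per layer: the input is corrupted by
#' Bernoulli zero-masking at probability `dropout`, passed through a
#' sigmoid encoding layer, and reconstructed by a sigmoid decoding
#' layer; parameters minimise the mean squared reconstruction error
#' against the *clean* input. Layers are pretrained greedily (layer
#' l + 1 trains on the clean encodings of layer l), then the unrolled
#' encoder–decoder is fine-tuned end-to-end on the same unsupervised
#' reconstruction objective.
#'
#' @param n_hidden Integer vector of encoder layer widths, input side
#'   first (e.g. `c(100, 30)`); its length is the number of layers.
#' @param dropout Corruption probability in `[0, 1]` (fraction of input
#'   coordinates forced to zero during training). Default 0.4.
#' @param batch_size Mini-batch size. Default 32.
#' @param pretrain_epochs Greedy pretraining epochs per layer.
#' @param fine_tune_epochs Unrolled fine-tuning epochs.
#' @param learning_rate Adam step size. Default 1e-3.
#' @param seed Integer seed controlling initialisation, shuffling and
#'   corruption masks.
#' @return An `sdae_config` list.
#' @examples
#' sdae_config(c(100, 30))
#' @export
sdae_config <- function(n_hidden, dropout = 0.4, batch_size = 32,
                        pretrain_epochs = 2, fine_tune_epochs = 2,
                        learning_rate = 1e-3, seed = 0) {
  n_hidden <- as.integer(n_hidden)
  if (length(n_hidden) < 1 || any(n_hidden < 1)) {
    abort("`n_hidden` must contain at least one positive layer width.",
          class = "harsdae_config_error")
  }
  if (dropout < 0 || dropout > 1) {
    abort("`dropout` must be in [0, 1].", class = "harsdae_config_error")
  }
  stopifnot(batch_size >= 1, learning_rate > 0,
            pretrain_epochs >= 0, fine_tune_epochs >= 0)
  structure(list(n_layer = length(n_hidden), n_hidden = n_hidden,
                 dropout = dropout, batch_size = as.integer(batch_size),
                 pretrain_epochs = as.integer(pretrain_epochs),
                 fine_tune_epochs = as.integer(fine_tune_epochs),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "sdae_config")
}

sigmoid <- function(z) stats::plogis(z)

#' Corrupt input by Bernoulli zero-masking
#'
#' Each coordinate is independently forced to zero with probability
#' `rate`; the rest pass through unchanged. Used only during training —
#' feature extraction sees clean inputs. Consumes the current RNG
#' stream.
#'
#' @param x Numeric vector or matrix.
#' @param rate Corruption probability in `[0, 1]`.
#' @return Object of the same shape as `x`.
#' @export
corrupt_input <- function(x, rate) {
  if (rate < 0 || rate > 1) {
    abort("`rate` must be in [0, 1].", class = "harsdae_config_error")
  }
  if (rate == 0) return(x)
  keep <- rbinom(length(x), 1, 1 - rate)
  if (is.matrix(x)) dim(keep) <- dim(x)
  x * keep
}

init_layer_params <- function(d_in, d_hidden) {
  lim_e <- sqrt(6 / (d_in + d_hidden))
  list(W_enc = matrix(runif(d_in * d_hidden, -lim_e, lim_e), d_in, d_hidden),
       b_enc = numeric(d_hidden),
       W_dec = matrix(runif(d_hidden * d_in, -lim_e, lim_e), d_hidden, d_in),
       b_dec = numeric(d_in))
}

as_row <- function(x) if (is.matrix(x)) x else matrix(x, 1)

#' Encoding and decoding layers
#'
#' `encode_layer()` maps inputs to the hidden representation through an
#' affine map followed by an elementwise sigmoid; `decode_layer()` maps
#' hidden values back to a reconstruction the same way (with the
#' transposed shape contract). Outputs lie in (0, 1), matching the
#' min-max standardised inputs.
#'
#' @param x Input vector or `(n, d_in)` matrix.
#' @param h Hidden vector or `(n, d_hidden)` matrix.
#' @param params Layer parameter list with `W_enc`, `b_enc`, `W_dec`,
#'   `b_dec`.
#' @return Matrix (or vector, matching the input form) of activations.
#' @export
encode_layer <- function(x, params) {
  xm <- as_row(x)
  if (ncol(xm) != nrow(params$W_enc)) {
    abort(sprintf("encode_layer: input width %d != expected %d.",
                  ncol(xm), nrow(params$W_enc)), class = "harsdae_shape_error")
  }
  out <- sigmoid(sweep(xm %*% params$W_enc, 2, params$b_enc, "+"))
  if (is.matrix(x)) out else drop(out)
}

#' @rdname encode_layer
#' @export
decode_layer <- function(h, params) {
  hm <- as_row(h)
  if (ncol(hm) != nrow(params$W_dec)) {
    abort(sprintf("decode_layer: input width %d != expected %d.",
                  ncol(hm), nrow(params$W_dec)), class = "harsdae_shape_error")
  }
  out <- sigmoid(sweep(hm %*% params$W_dec, 2, params$b_dec, "+"))
  if (is.matrix(h)) out else drop(out)
}

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_update <- function(params, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

dae_loss <- function(x, params, rate = 0) {
  xc <- corrupt_input(x, rate)
  r <- decode_layer(encode_layer(xc, params), params)
  mean((r - as_row(x))^2)
}

#' Pretrain one denoising autoencoder layer
#'
#' Minimises the mean squared error between the decoded reconstruction
#' of the corrupted input and the clean input, by mini-batch gradient
#' descent with Adam. Reproducible under the config seed (offset by the
#' layer index so layers draw distinct streams).
#'
#' @param data `(n, d)` matrix of layer inputs — standardised samples
#'   for layer 1, clean encodings of the previous layer above that.
#' @param config An [sdae_config()].
#' @param layer_index Which layer of `config$n_hidden` to train.
#' @return Layer parameter list with a `loss_history` attribute (mean
#'   epoch training loss, length `pretrain_epochs`).
#' @export
pretrain_layer <- function(data, config, layer_index) {
  d_in <- ncol(data)
  width <- config$n_hidden[layer_index]
  withr::with_seed(config$seed + layer_index, {
    params <- init_layer_params(d_in, width)
    state <- adam_state(params)
    history <- numeric(0)
    n <- nrow(data)
    for (epoch in seq_len(config$pretrain_epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (b_start in seq(1, n, by = config$batch_size)) {
        idx <- ord[b_start:min(b_start + config$batch_size - 1, n)]
        x <- data[idx, , drop = FALSE]
        xc <- corrupt_input(x, config$dropout)
        h <- encode_layer(xc, params)
        r <- decode_layer(h, params)
        loss <- mean((r - x)^2)
        if (!is.finite(loss)) {
          abort("Non-finite pretraining loss (training diverged).",
                class = "harsdae_divergence_error")
        }
        losses <- c(losses, loss)
        dr <- 2 * (r - x) / length(r)
        dz2 <- dr * r * (1 - r)
        dh <- dz2 %*% t(params$W_dec)
        dz1 <- dh * h * (1 - h)
        grads <- list(W_enc = t(xc) %*% dz1, b_enc = colSums(dz1),
                      W_dec = t(h) %*% dz2, b_dec = colSums(dz2))
        upd <- adam_update(params, grads, state, config$learning_rate)
        params <- upd$params
        state <- upd$state
      }
      history <- c(history, mean(losses))
    }
    attr(params, "loss_history") <- history
    params
  })
}

#' Build a stacked denoising autoencoder by greedy pretraining
#'
#' Trains layer 1 on the standardised samples, then trains each further
#' layer on the *clean* (uncorrupted) encodings of the layer below —
#' corruption is re-applied per layer during its own pretraining only.
#'
#' @param train `(n, d)` matrix of standardised training samples for one
#'   sensor.
#' @param config An [sdae_config()].
#' @return An `sdae` object: ordered layer parameters, the config, and
#'   per-layer pretraining loss histories.
#' @export
build_stack <- function(train, config) {
  stopifnot(inherits(config, "sdae_config"))
  layers <- vector("list", config$n_layer)
  losses <- vector("list", config$n_layer)
  current <- train
  for (l in seq_len(config$n_layer)) {
    layers[[l]] <- pretrain_layer(current, config, l)
    losses[[l]] <- attr(layers[[l]], "loss_history")
    current <- encode_layer(current, layers[[l]])
  }
  structure(list(layers = layers, config = config,
                 pretrain_loss = losses, fine_tune_loss = numeric(0)),
            class = "sdae")
}

unrolled_forward <- function(x, layers) {
  acts <- vector("list", 2 * length(layers) + 1)
  acts[[1]] <- x
  a <- x
  for (l in seq_along(layers)) {
    a <- encode_layer(a, layers[[l]])
    acts[[l + 1]] <- a
  }
  for (l in rev(seq_along(layers))) {
    a <- decode_layer(a, layers[[l]])
    acts[[2 * length(layers) - l + 2]] <- a
  }
  acts
}

#' Fine-tune the unrolled encoder–decoder end-to-end
#'
#' Unrolls the stack (all encoders, then the decoders in reverse order)
#' and trains every parameter jointly on the corrupted-input
#' reconstruction MSE against the clean samples. With zero fine-tune
#' epochs the stack is returned unchanged.
#'
#' @param stack An `sdae` from [build_stack()].
#' @param train The same training sample matrix used for pretraining.
#' @param config Optional [sdae_config()] override (defaults to the
#'   stack's own config).
#' @return The updated `sdae`, with `fine_tune_loss` the epoch loss
#'   history.
#' @export
fine_tune_stack <- function(stack, train, config = stack$config) {
  L <- length(stack$layers)
  layers <- stack$layers
  withr::with_seed(config$seed + 1000L, {
    flat <- unlist(layers, recursive = FALSE)
    names(flat) <- paste0(rep(seq_len(L), each = 4), "_",
                          rep(c("W_enc", "b_enc", "W_dec", "b_dec"), L))
    state <- adam_state(flat)
    history <- numeric(0)
    n <- nrow(train)
    for (epoch in seq_len(config$fine_tune_epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (b_start in seq(1, n, by = config$batch_size)) {
        idx <- ord[b_start:min(b_start + config$batch_size - 1, n)]
        x <- train[idx, , drop = FALSE]
        xc <- corrupt_input(x, config$dropout)
        acts <- unrolled_forward(xc, layers)
        r <- acts[[2 * L + 1]]
        loss <- mean((r - x)^2)
        if (!is.finite(loss)) {
          abort("Non-finite fine-tuning loss (training diverged).",
                class = "harsdae_divergence_error")
        }
        losses <- c(losses, loss)
        grads <- lapply(flat, function(p) p * 0)
        delta <- 2 * (r - x) / length(r)
        # decoder side: layer order L..1 maps to activations acts[L+1..2L]
        for (l in seq_len(L)) {
          a_out <- acts[[2 * L - l + 2]]          # output of decoder l
          a_in <- acts[[2 * L - l + 1]]           # its input activation
          dz <- delta * a_out * (1 - a_out)
          grads[[paste0(l, "_W_dec")]] <- t(a_in) %*% dz
          grads[[paste0(l, "_b_dec")]] <- colSums(dz)
          delta <- dz %*% t(layers[[l]]$W_dec)
        }
        for (l in rev(seq_len(L))) {
          a_out <- acts[[l + 1]]
          a_in <- acts[[l]]
          dz <- delta * a_out * (1 - a_out)
          grads[[paste0(l, "_W_enc")]] <- t(a_in) %*% dz
          grads[[paste0(l, "_b_enc")]] <- colSums(dz)
          delta <- dz %*% t(layers[[l]]$W_enc)
        }
        upd <- adam_update(flat, grads, state, config$learning_rate)
        flat <- upd$params
        state <- upd$state
        for (l in seq_len(L)) {
          layers[[l]] <- list(W_enc = flat[[paste0(l, "_W_enc")]],
                              b_enc = flat[[paste0(l, "_b_enc")]],
                              W_dec = flat[[paste0(l, "_W_dec")]],
                              b_dec = flat[[paste0(l, "_b_dec")]])
        }
      }
      history <- c(history, mean(losses))
    }
    stack$layers <- layers
    stack$fine_tune_loss <- history
    stack
  })
}

#' Unrolled reconstruction error of a stack
#'
#' Mean squared error of the full encode–decode round trip on clean
#' inputs; used to verify that fine-tuning improves the stack.
#'
#' @param stack An `sdae`.
#' @param x Sample matrix.
#' @return A single number.
#' @export
reconstruction_mse <- function(stack, x) {
  acts <- unrolled_forward(as_row(x), stack$layers)
  mean((acts[[length(acts)]] - as_row(x))^2)
}

#' Extract learned features with the encoder composition
#'
#' Applies every encoding layer in order, with no corruption — feature
#' extraction is deterministic given a trained stack. The output width
#' equals the top layer width.
#'
#' @param stack An `sdae`.
#' @param x `(n, d)` matrix with `d` equal to the layer-1 input width.
#' @return `(n, top_width)` feature matrix.
#' @export
extract_features <- function(stack, x) {
  if (length(stack$layers) == 0) {
    abort("Cannot extract features from an empty stack.",
          class = "harsdae_config_error")
  }
  a <- as_row(x)
  for (p in stack$layers) a <- encode_layer(a, p)
  a
}

#' Concatenate per-sensor feature matrices
#'
#' Column-binds the learned features of each sensor in the given, fixed
#' order; all sensors must have extracted features for the same windows.
#'
#' @param per_sensor Named list of `(n, f_k)` matrices.
#' @return `(n, sum f_k)` matrix with `sensor.j` column names.
#' @export
concat_sensor_features <- function(per_sensor) {
  ns <- vapply(per_sensor, nrow, integer(1))
  if (length(unique(ns)) != 1) {
    abort("Per-sensor feature matrices have differing row counts.",
          class = "harsdae_alignment_error")
  }
  out <- do.call(cbind, unname(per_sensor))
  colnames(out) <- unlist(lapply(names(per_sensor), function(s) {
    paste0(s, ".", seq_len(ncol(per_sensor[[s]])))
  }))
  out
}

#' Fit one stacked denoising autoencoder per sensor
#'
#' The end-to-end unsupervised feature-extraction step: for every
#' sensor matrix-column of a (standardised) `har_windows` table, builds
#' and fine-tunes an independent SDAE.
#'
#' @param windows Standardised training `har_windows` tibble.
#' @param config An [sdae_config()] shared by all sensors, or a named
#'   list with one config per sensor (e.g. a narrower stack for a
#'   single-axis barometer).
#' @return An `sdae_set`: named list of `sdae` objects.
#' @export
fit_sdae <- function(windows, config) {
  sensors <- sensor_names(windows)
  configs <- if (inherits(config, "sdae_config")) {
    stats::setNames(rep(list(config), length(sensors)), sensors)
  } else config
  stopifnot(all(sensors %in% names(configs)))
  stacks <- lapply(sensors, function(s) {
    st <- build_stack(windows[[s]], configs[[s]])
    fine_tune_stack(st, windows[[s]])
  })
  names(stacks) <- sensors
  structure(stacks, class = "sdae_set")
}

#' Extract and concatenate features for a whole sample table
#'
#' @param windows A `har_windows` tibble (standardised with the training
#'   scaler).
#' @param stacks An `sdae_set` from [fit_sdae()].
#' @return A `har_features` tibble: `window_id`, `recording_id`,
#'   `activity` and a `features` matrix-column.
#' @export
features_from_windows <- function(windows, stacks) {
  per_sensor <- lapply(stats::setNames(nm = names(stacks)), function(s) {
    extract_features(stacks[[s]], windows[[s]])
  })
  keep <- intersect(c("window_id", "recording_id", "activity"), names(windows))
  out <- tibble::as_tibble(windows[keep])
  out$features <- concat_sensor_features(per_sensor)
  class(out) <- c("har_features", class(out))
  out
}
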