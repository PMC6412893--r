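#' Read one recording CSV
#'
#' Expects the contract written by [write_recording_csv()]: a header of
#' `<sensor>_<axis>` columns (for every sensor declared in `schema`)
#' plus a `label` column, one row per timestamp. All sensors share the
#' clock, so every declared axis must be present on every row.
#'
#' @param path CSV file path.
#' @param schema Sensor schema tibble (see [sensor_spec()]).
#' @return A wide signal tibble with the schema's axis columns and an
#'   `activity` column.
#' @export
read_recording <- function(path, schema) {
  check_schema(schema)
  if (!file.exists(path)) {
    abort(paste0("No such recording file: ", path), class = "harsdae_io_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(readr::problems(df)) > 0) {
    abort(paste0("Malformed (ragged) rows in ", path),
          class = "harsdae_format_error")
  }
  wanted <- unlist(lapply(seq_len(nrow(schema)),
                          function(k) sensor_columns(schema[k, ])))
  missing <- setdiff(c(wanted, "label"), names(df))
  if (length(missing) > 0) {
    abort(paste0("Recording is missing schema columns: ",
                 paste(missing, collapse = ", ")),
          class = "harsdae_schema_error")
  }
  df <- df[c(wanted, "label")]
  if (anyNA(df)) {
    abort(paste0("Missing values in ", path), class = "harsdae_format_error")
  }
  names(df)[names(df) == "label"] <- "activity"
  df$activity <- as.character(df$activity)
  tibble::as_tibble(df)
}

window_starts <- function(n_samples, window_len, stride) {
  if (n_samples < window_len) return(integer(0))
  # emit a window iff start + window_len <= n_samples (0-based starts)
  seq.int(0L, n_samples - window_len, by = stride)
}

#' Segment one recording into per-sensor window tensors
#'
#' Slides a window of `window_len` samples with step `stride` over the
#' shared clock and cuts every sensor at the same starts, so windows
#' never mix timestamps across sensors. The number of windows emitted is
#' `floor((T - w) / s) + 1` for a recording of `T` samples; a recording
#' shorter than one window yields zero windows with a warning.
#'
#' @param recording Wide signal tibble (one recording).
#' @param schema Sensor schema tibble.
#' @param window_len Window length `w` in samples.
#' @param stride Step `s` in samples, `1 <= stride <= window_len`.
#' @return Named list (one entry per sensor) of arrays with dimensions
#'   `(n_windows, window_len, n_axes)`.
#' @export
segment_windows <- function(recording, schema, window_len, stride) {
  check_schema(schema)
  if (stride < 1 || stride > window_len) {
    abort("`stride` must satisfy 1 <= stride <= window_len.",
          class = "harsdae_config_error")
  }
  n <- nrow(recording)
  starts <- window_starts(n, window_len, stride)
  if (length(starts) == 0) {
    warn(sprintf("Recording of %d samples is shorter than one %d-sample window; no windows emitted.",
                 n, window_len))
  }
  out <- list()
  for (k in seq_len(nrow(schema))) {
    sp <- schema[k, ]
    cols <- sensor_columns(sp)
    sig <- as.matrix(recording[cols])
    arr <- array(0, dim = c(length(starts), window_len, sp$n_axes))
    for (i in seq_along(starts)) {
      arr[i, , ] <- sig[starts[i] + seq_len(window_len), , drop = FALSE]
    }
    out[[sp$name]] <- arr
  }
  out
}

#' Flatten window tensors to sample matrices (and back)
#'
#' Reshapes an `(N, w, d)` window tensor to an `(N, w * d)` sample
#' matrix by splicing along the axis dimension: within a row, the `d`
#' axis values of timestamp 1 come first, then timestamp 2, and so on.
#' `unflatten_windows()` is the exact inverse.
#'
#' @param windows Array of dimension `(N, w, d)`.
#' @return An `(N, w * d)` numeric matrix.
#' @export
flatten_windows <- function(windows) {
  stopifnot(length(dim(windows)) == 3)
  d <- dim(windows)
  out <- matrix(0, d[1], d[2] * d[3])
  for (i in seq_len(d[1])) {
    out[i, ] <- as.vector(t(windows[i, , ]))
  }
  out
}

#' @rdname flatten_windows
#' @param flat An `(N, w * d)` matrix produced by [flatten_windows()].
#' @param window_len,n_axes Original tensor dimensions `w` and `d`.
#' @export
unflatten_windows <- function(flat, window_len, n_axes) {
  stopifnot(ncol(flat) == window_len * n_axes)
  arr <- array(0, dim = c(nrow(flat), window_len, n_axes))
  for (i in seq_len(nrow(flat))) {
    arr[i, , ] <- matrix(flat[i, ], window_len, n_axes, byrow = TRUE)
  }
  arr
}

#' Window a whole dataset of recordings into flat labelled samples
#'
#' Applies [segment_windows()] and [flatten_windows()] per recording
#' (windows never span two recordings) and pools the result into one
#' tidy sample table: one row per window, with the per-sensor flattened
#' samples stored as matrix-columns named after the sensors.
#'
#' @param dataset Nested recording tibble as returned by
#'   [simulate_har_dataset()] (columns `recording_id`, `activity`,
#'   `signals`).
#' @param schema Sensor schema tibble.
#' @inheritParams segment_windows
#' @return A `har_windows` tibble with columns `window_id`,
#'   `recording_id`, `activity` and one `(N, w * d_k)` matrix-column per
#'   sensor.
#' @examples
#' ds <- simulate_har_dataset(duration = 3, recordings_per_class = 2, seed = 1)
#' w <- windows_from_recordings(ds, schema_imu(50), 64, 64)
#' dim(w$acc)
#' @export
windows_from_recordings <- function(dataset, schema, window_len = 128,
                                    stride = window_len) {
  check_schema(schema)
  pieces <- purrr::pmap(dataset, function(recording_id, activity, signals, ...) {
    tens <- segment_windows(signals, schema, window_len, stride)
    n_win <- dim(tens[[1]])[1]
    if (n_win == 0) return(NULL)
    row <- tibble::tibble(recording_id = rep(recording_id, n_win),
                          activity = rep(activity, n_win))
    for (s in names(tens)) row[[s]] <- flatten_windows(tens[[s]])
    row
  })
  out <- dplyr::bind_rows(purrr::compact(pieces))
  out <- dplyr::bind_cols(tibble::tibble(window_id = seq_len(nrow(out))), out)
  class(out) <- c("har_windows", class(out))
  attr(out, "schema") <- schema
  attr(out, "window_len") <- as.integer(window_len)
  attr(out, "stride") <- as.integer(stride)
  out
}

sensor_names <- function(windows) {
  names(windows)[vapply(windows, is.matrix, logical(1))]
}

#' Min-max standardisation fitted on training samples
#'
#' `fit_minmax()` records the exact per-column minimum and maximum of
#' the training samples; `apply_minmax()` maps each column through
#' `(x - min) / (max - min)`. Training data therefore lands in `[0, 1]`
#' with exact 0/1 extrema; data standardised with a scaler fitted
#' elsewhere (e.g. test data) reuses the training extrema and may fall
#' outside `[0, 1]` — it is deliberately not clipped. A constant column
#' (max == min) maps to all zeros.
#'
#' @param x A `har_windows` tibble (all sensor matrix-columns are
#'   fitted) or a plain numeric matrix.
#' @return For `fit_minmax`, a `har_scaler` (per-sensor column extrema);
#'   for `apply_minmax`, `x` with standardised values.
#' @examples
#' sc <- fit_minmax(matrix(c(0, 5, 10), 3))
#' apply_minmax(matrix(12), sc)
#' @export
fit_minmax <- function(x) UseMethod("fit_minmax")

#' @export
fit_minmax.matrix <- function(x) {
  stopifnot(nrow(x) >= 1)
  p <- list(min = apply(x, 2, min), max = apply(x, 2, max))
  class(p) <- "har_scaler"
  p
}

#' @export
fit_minmax.har_windows <- function(x) {
  p <- lapply(x[sensor_names(x)], fit_minmax)
  class(p) <- c("har_scaler_set", "har_scaler")
  p
}

scale_minmax_matrix <- function(x, p) {
  if (ncol(x) != length(p$min)) {
    abort("Column count does not match the fitted scaler.",
          class = "harsdae_shape_error")
  }
  rng <- p$max - p$min
  rng[rng == 0] <- 1   # constant training column -> 0 everywhere
  sweep(sweep(x, 2, p$min, "-"), 2, rng, "/")
}

#' @rdname fit_minmax
#' @param params A scaler returned by `fit_minmax()`.
#' @export
apply_minmax <- function(x, params) UseMethod("apply_minmax")

#' @export
apply_minmax.matrix <- function(x, params) scale_minmax_matrix(x, params)

#' @export
apply_minmax.har_windows <- function(x, params) {
  stopifnot(inherits(params, "har_scaler_set"))
  for (s in sensor_names(x)) {
    x[[s]] <- scale_minmax_matrix(x[[s]], params[[s]])
  }
  x
}

#' Stratified train/test split of windowed samples
#'
#' Partitions the windows into disjoint, exhaustive train and test sets,
#' stratified by activity so class priors stay comparable between the
#' partitions, reproducibly under `seed`.
#'
#' @param windows A `har_windows` tibble (or any data frame with an
#'   `activity` column).
#' @param test_fraction Proportion held out for testing, in (0, 1).
#' @param seed Integer seed.
#' @return A list with elements `train` and `test`.
#' @export
split_train_test <- function(windows, test_fraction = 0.3, seed = 0) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    abort("`test_fraction` must be in (0, 1).", class = "harsdae_config_error")
  }
  y <- windows$activity
  counts <- table(y)
  if (any(counts < 2)) {
    abort(paste0("Cannot stratify: class(es) with fewer than 2 samples: ",
                 paste(names(counts)[counts < 2], collapse = ", ")),
          class = "harsdae_stratify_error")
  }
  test_idx <- withr::with_seed(seed, {
    unlist(lapply(split(seq_along(y), y), function(idx) {
      n_test <- round(length(idx) * test_fraction)
      n_test <- max(1L, min(length(idx) - 1L, n_test))
      sample(idx, n_test)
    }), use.names = FALSE)
  })
  list(train = windows[-sort(test_idx), , drop = FALSE],
       test = windows[sort(test_idx), , drop = FALSE])
}
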