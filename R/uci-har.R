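#' Read the UCI smartphone activity-recognition layout
#'
#' Reads the public "Inertial Signals" directory layout: per split
#' (`train`/`test`), nine whitespace-delimited text files of 128
#' columns each — `body_acc`, `body_gyro` and `total_acc`, one file per
#' axis — holding pre-cut 2.56 s windows at 50 Hz, plus `y_<split>.txt`
#' with 1-based integer class labels and (optionally)
#' `activity_labels.txt` mapping them to names.
#'
#' @param dir Dataset root containing `train/` and/or `test/`.
#' @param split `"train"` or `"test"`.
#' @return A `har_windows` tibble with matrix-columns `body_acc`,
#'   `body_gyro`, `total_acc` (each `(N, 384)`, windows flattened
#'   axis-within-timestamp) and an `activity` column.
#' @export
read_uci_har <- function(dir, split = c("train", "test")) {
  split <- match.arg(split)
  sig_dir <- file.path(dir, split, "Inertial Signals")
  if (!dir.exists(sig_dir)) {
    abort(paste0("No 'Inertial Signals' directory under ", file.path(dir, split)),
          class = "harsdae_io_error")
  }
  sensors <- c("body_acc", "body_gyro", "total_acc")
  axes <- c("x", "y", "z")
  read_sig <- function(sensor, axis) {
    f <- file.path(sig_dir, sprintf("%s_%s_%s.txt", sensor, axis, split))
    if (!file.exists(f)) {
      abort(paste0("Missing signal file: ", f), class = "harsdae_io_error")
    }
    as.matrix(utils::read.table(f))
  }
  y_file <- file.path(dir, split, sprintf("y_%s.txt", split))
  labels <- as.integer(utils::read.table(y_file)[[1]])
  lab_file <- file.path(dir, "activity_labels.txt")
  if (file.exists(lab_file)) {
    map <- utils::read.table(lab_file, col.names = c("id", "name"))
    activity <- map$name[match(labels, map$id)]
  } else {
    activity <- as.character(labels)
  }
  out <- tibble::tibble(window_id = seq_along(labels),
                        recording_id = NA_character_,
                        activity = as.character(activity))
  for (s in sensors) {
    per_axis <- lapply(axes, function(a) read_sig(s, a))
    n <- nrow(per_axis[[1]])
    w <- ncol(per_axis[[1]])
    arr <- array(0, dim = c(n, w, 3))
    for (a in 1:3) arr[, , a] <- per_axis[[a]]
    out[[s]] <- flatten_windows(arr)
  }
  class(out) <- c("har_windows", class(out))
  attr(out, "schema") <- dplyr::bind_rows(
    sensor_spec("body_acc", 3, 50), sensor_spec("body_gyro", 3, 50),
    sensor_spec("total_acc", 3, 50))
  attr(out, "window_len") <- 128L
  attr(out, "stride") <- 128L
  out
}
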