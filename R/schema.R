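#' Describe one body-worn sensor stream
#'
#' A sensor schema row records the short name of a sensor (e.g. `"acc"`),
#' how many synchronised axes it reports and its sampling rate in Hz.
#' Recordings are stored as wide data frames with one column per sensor
#' axis, named `<sensor>_<axis>` with axis letters `x`, `y`, `z` (a
#' single-axis sensor such as a barometer uses the suffix `v`).
#'
#' @param name Short sensor identifier, used as the column-name prefix.
#' @param n_axes Number of axes (>= 1).
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @return A one-row tibble with columns `name`, `n_axes`, `sampling_rate`.
#' @examples
#' sensor_spec("acc", 3, 50)
#' @export
sensor_spec <- function(name, n_axes, sampling_rate) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (n_axes < 1 || n_axes != round(n_axes)) {
    abort("`n_axes` must be a positive integer.", class = "harsdae_schema_error")
  }
  if (sampling_rate <= 0) {
    abort("`sampling_rate` must be positive.", class = "harsdae_schema_error")
  }
  tibble::tibble(name = name, n_axes = as.integer(n_axes),
                 sampling_rate = as.numeric(sampling_rate))
}

#' Default smartphone sensor schemas
#'
#' `schema_imu()` is the triaxial accelerometer + gyroscope + magnetometer
#' cluster; `schema_imu_baro()` adds a single-axis barometric pressure
#' channel (used for vertical-transport activities such as elevators).
#'
#' @param sampling_rate Sampling rate in Hz shared by all sensors.
#' @return A sensor schema tibble (one row per sensor).
#' @examples
#' schema_imu(50)
#' @export
schema_imu <- function(sampling_rate = 50) {
  dplyr::bind_rows(
    sensor_spec("acc", 3, sampling_rate),
    sensor_spec("gyro", 3, sampling_rate),
    sensor_spec("mag", 3, sampling_rate)
  )
}

#' @rdname schema_imu
#' @export
schema_imu_baro <- function(sampling_rate = 100) {
  dplyr::bind_rows(schema_imu(sampling_rate),
                   sensor_spec("baro", 1, sampling_rate))
}

axis_letters <- function(n_axes) {
  if (n_axes == 1L) return("v")
  c("x", "y", "z", letters[23:1])[seq_len(n_axes)]
}

#' Column names of one sensor in a wide recording
#'
#' @param spec A one-row sensor schema (see [sensor_spec()]).
#' @return Character vector `<name>_<axis>` of length `n_axes`.
#' @keywords internal
sensor_columns <- function(spec) {
  paste(spec$name, axis_letters(spec$n_axes), sep = "_")
}

check_schema <- function(schema) {
  required <- c("name", "n_axes", "sampling_rate")
  if (!is.data.frame(schema) || !all(required %in% names(schema)) ||
      nrow(schema) < 1L) {
    abort("`schema` must be a sensor schema tibble with columns name, n_axes, sampling_rate.",
          class = "harsdae_schema_error")
  }
  if (anyDuplicated(schema$name)) {
    abort("Sensor names in `schema` must be unique.", class = "harsdae_schema_error")
  }
  invisible(schema)
}
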