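#' Per-class sample counts of the three benchmark smartphone datasets
#'
#' The published per-class window counts of the moving-modes (HMM),
#' static-behaviour (HSBD) and dynamic-behaviour / postural-transition
#' (HDBD) smartphone activity datasets, with the percentage share of
#' each class as printed in the source study's summary (`printed_pct`).
#' Note the printed shares were truncated rather than rounded to two
#' decimals (e.g. 1325/10663 = 12.426% printed as 12.42%), so
#' recomputed shares can differ by up to 0.01 percentage points.
#'
#' @return A tibble with columns `dataset`, `category`, `abbrev`,
#'   `n_samples`, `printed_pct`.
#' @examples
#' activity_class_counts()
#' @export
activity_class_counts <- function() {
  readr::read_csv(system.file("extdata", "activity_class_counts.csv",
                              package = "harsdae"),
                  show_col_types = FALSE, progress = FALSE)
}

#' Class percentage shares from per-class counts
#'
#' Recomputes each class's share of its dataset,
#' `100 * n / sum(n within dataset)`, at full precision.
#'
#' @param counts A data frame with at least `dataset` and `n_samples`
#'   columns (defaults to [activity_class_counts()]).
#' @return The input tibble with a `share_pct` column appended.
#' @examples
#' class_shares()
#' @export
class_shares <- function(counts = activity_class_counts()) {
  counts |>
    dplyr::group_by(.data$dataset) |>
    dplyr::mutate(share_pct = 100 * .data$n_samples / sum(.data$n_samples)) |>
    dplyr::ungroup()
}
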