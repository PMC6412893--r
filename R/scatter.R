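#' Within- and between-class scatter matrices
#'
#' Class-separability diagnostics. For class i with samples `x` and
#' mean `m_i`, the inner-class (within) scatter is the biased second
#' moment `S_W(i) = (1/N_i) * sum (x - m_i)(x - m_i)^T`; the total
#' inner-class scatter weights these by the empirical class priors
#' `P_i = N_i / N`. The outer-class (between) scatter of a class pair is
#' the rank-one outer product of the mean difference,
#' `S_B(ij) = (m_i - m_j)(m_i - m_j)^T`, and the total between-class
#' scatter is `S_B = 1/2 * sum_ij P_i P_j S_B(ij)`, which equals the
#' prior-weighted scatter of class means about the grand mean. Traces
#' of these matrices measure class compactness and separation: a good
#' feature space has small `tr(S_W)` and large `tr(S_B)`.
#'
#' @param x `(n, d)` sample or feature matrix.
#' @param y Length-`n` class label vector.
#' @param class_i,class_j Class labels present in `y`.
#' @return `class_scatter()`: list with `mean`, `scatter`, `trace` and
#'   the class size `n`. `total_inner_scatter()` /
#'   `total_outer_scatter()`: list with `scatter` and `trace`.
#'   `pairwise_outer_scatter()`: list with `scatter` and `trace`.
#' @examples
#' x <- rbind(c(0, 0), c(2, 0))
#' class_scatter(x, c("a", "a"), "a")$trace
#' @export
class_scatter <- function(x, y, class_i) {
  x <- as.matrix(x)
  idx <- which(y == class_i)
  if (length(idx) == 0) {
    abort(paste0("Unknown class: ", class_i), class = "harsdae_class_error")
  }
  xi <- x[idx, , drop = FALSE]
  m <- colMeans(xi)
  centered <- sweep(xi, 2, m)
  sw <- crossprod(centered) / nrow(xi)   # biased 1/N_i normalisation
  list(mean = m, scatter = sw, trace = sum(diag(sw)), n = nrow(xi))
}

#' @rdname class_scatter
#' @export
total_inner_scatter <- function(x, y) {
  x <- as.matrix(x)
  classes <- unique(y)
  sw <- matrix(0, ncol(x), ncol(x))
  for (ci in classes) {
    cs <- class_scatter(x, y, ci)
    sw <- sw + (cs$n / nrow(x)) * cs$scatter
  }
  list(scatter = sw, trace = sum(diag(sw)))
}

#' @rdname class_scatter
#' @export
pairwise_outer_scatter <- function(x, y, class_i, class_j) {
  mi <- class_scatter(x, y, class_i)$mean
  mj <- class_scatter(x, y, class_j)$mean
  d <- mi - mj
  sb <- tcrossprod(d)
  list(scatter = sb, trace = sum(d^2))
}

#' @rdname class_scatter
#' @export
total_outer_scatter <- function(x, y) {
  x <- as.matrix(x)
  classes <- unique(y)
  priors <- vapply(classes, function(ci) mean(y == ci), numeric(1))
  means <- lapply(classes, function(ci) class_scatter(x, y, ci)$mean)
  sb <- matrix(0, ncol(x), ncol(x))
  for (i in seq_along(classes)) {
    for (j in seq_along(classes)) {
      d <- means[[i]] - means[[j]]
      sb <- sb + 0.5 * priors[i] * priors[j] * tcrossprod(d)
    }
  }
  list(scatter = sb, trace = sum(diag(sb)))
}

scatter_trace_table <- function(x, y) {
  classes <- sort(unique(y))
  tab <- matrix(0, length(classes), length(classes),
                dimnames = list(classes, classes))
  for (i in seq_along(classes)) {
    for (j in seq_along(classes)) {
      tab[i, j] <- if (i == j) {
        class_scatter(x, y, classes[i])$trace
      } else {
        pairwise_outer_scatter(x, y, classes[i], classes[j])$trace
      }
    }
  }
  tab
}

#' Compare class separability of raw samples and extracted features
#'
#' Emits the trace summaries used to judge a feature extractor: total
#' inner- and outer-class scatter traces for both representations, and
#' per-space symmetric class tables with inner-class traces on the
#' diagonal and pairwise between-class traces off it.
#'
#' @param raw `(n, d_raw)` matrix of standardised raw samples.
#' @param features `(n, d_feat)` matrix of extracted features for the
#'   same windows.
#' @param y Length-`n` class labels.
#' @return A `har_divergence` list: `totals` (tibble with columns
#'   `space`, `inner_trace`, `outer_trace`) and `tables` (named list of
#'   two class-by-class trace matrices).
#' @export
divergence_report <- function(raw, features, y) {
  spaces <- list(raw = as.matrix(raw), features = as.matrix(features))
  totals <- purrr::map_dfr(names(spaces), function(nm) {
    tibble::tibble(space = nm,
                   inner_trace = total_inner_scatter(spaces[[nm]], y)$trace,
                   outer_trace = total_outer_scatter(spaces[[nm]], y)$trace)
  })
  tables <- lapply(spaces, scatter_trace_table, y = y)
  structure(list(totals = totals, tables = tables), class = "har_divergence")
}

#' @export
print.har_divergence <- function(x, ...) {
  cat("Class-separability report (scatter-matrix traces)\n")
  print(x$totals)
  invisible(x)
}
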