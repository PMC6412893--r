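#' Confusion matrix
#'
#' Counts of truth (rows) against prediction (columns) over a fixed
#' class order.
#'
#' @param y_true,y_pred Label vectors of equal length.
#' @param class_order Optional class ordering; defaults to the sorted
#'   union of observed labels.
#' @param normalize If `TRUE`, rows are normalised to per-class
#'   proportions (rows summing to 1; empty truth rows stay 0).
#' @return An `M x M` matrix with `dimnames` = classes.
#' @examples
#' confusion(c(0, 0, 1, 1), c(0, 1, 1, 1))
#' @export
confusion <- function(y_true, y_pred, class_order = NULL, normalize = FALSE) {
  stopifnot(length(y_true) == length(y_pred))
  if (is.null(class_order)) {
    class_order <- sort(unique(c(as.character(y_true), as.character(y_pred))))
  }
  cm <- table(factor(as.character(y_true), levels = class_order),
              factor(as.character(y_pred), levels = class_order))
  cm <- unclass(as.matrix(cm))
  names(dimnames(cm)) <- NULL
  if (normalize) {
    rs <- rowSums(cm)
    rs[rs == 0] <- 1
    cm <- cm / rs
  }
  cm
}

#' Macro-averaged precision, recall and F1 from a confusion matrix
#'
#' Per class k: precision `P_k = TP / (TP + FP)`, recall
#' `R_k = TP / (TP + FN)` and `F1_k = 2 P_k R_k / (P_k + R_k)`; the
#' macro scores are their unweighted means over classes, and accuracy
#' is the diagonal fraction. A class never predicted (or absent from
#' the truth) would divide by zero; its metric is defined as 0 and a
#' warning is raised.
#'
#' @param cm Confusion matrix of counts (rows = truth), e.g. from
#'   [confusion()].
#' @return A `har_eval` list: `confusion`, `accuracy`, `per_class`
#'   (tibble of `class`, `precision`, `recall`, `f1`), and macro
#'   `precision`, `recall`, `f1`.
#' @examples
#' macro_prf(confusion(c(0, 0, 1, 1), c(0, 1, 1, 1)))
#' @export
macro_prf <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm))
  total <- sum(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(num, den, what) {
    out <- ifelse(den == 0, 0, num / den)
    if (any(den == 0)) {
      warn(paste0("Zero denominator in ", what,
                  " for class(es): ",
                  paste(rownames(cm)[den == 0], collapse = ", "),
                  "; metric set to 0."))
    }
    out
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- safe_div(2 * precision * recall, precision + recall, "F1")
  per_class <- tibble::tibble(class = rownames(cm) %||% as.character(seq_len(nrow(cm))),
                              precision = unname(precision),
                              recall = unname(recall), f1 = unname(f1))
  structure(list(confusion = cm,
                 accuracy = sum(tp) / total,
                 per_class = per_class,
                 precision = mean(precision), recall = mean(recall),
                 f1 = mean(f1)),
            class = "har_eval")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate predictions against truth
#'
#' @param y_true,y_pred Label vectors.
#' @param class_order Optional fixed class order for the confusion
#'   matrix.
#' @return A `har_eval` (see [macro_prf()]).
#' @export
evaluate_predictions <- function(y_true, y_pred, class_order = NULL) {
  macro_prf(confusion(y_true, y_pred, class_order))
}

#' @export
print.har_eval <- function(x, digits = 4, ...) {
  cat(sprintf("Accuracy %.4f | macro P %.4f R %.4f F1 %.4f (%d classes, %d samples)\n",
              x$accuracy, x$precision, x$recall, x$f1,
              nrow(x$per_class), sum(x$confusion)))
  invisible(x)
}
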