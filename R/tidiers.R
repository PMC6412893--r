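#' Tidy and glance methods
#'
#' Broom-style summaries of the package's fitted objects: `tidy()`
#' returns one row per component (training epoch, fold, class or
#' space), `glance()` a one-row model summary.
#'
#' @param x A fitted object (`sdae`, `boost_kfold`, `har_eval`,
#'   `har_divergence` or `single_sdae`).
#' @param ... Unused, for generic consistency.
#' @return A tibble.
#' @name harsdae-tidiers
NULL

#' @rdname harsdae-tidiers
#' @method tidy sdae
#' @export
tidy.sdae <- function(x, ...) {
  pre <- purrr::imap_dfr(x$pretrain_loss, function(losses, l) {
    tibble::tibble(stage = "pretrain", layer = l,
                   epoch = seq_along(losses), loss = losses)
  })
  ft <- tibble::tibble(stage = "fine_tune", layer = NA_integer_,
                       epoch = seq_along(x$fine_tune_loss),
                       loss = x$fine_tune_loss)
  dplyr::bind_rows(pre, ft)
}

#' @rdname harsdae-tidiers
#' @method glance sdae
#' @export
glance.sdae <- function(x, ...) {
  tibble::tibble(n_layer = x$config$n_layer,
                 input_dim = nrow(x$layers[[1]]$W_enc),
                 feature_dim = ncol(x$layers[[length(x$layers)]]$W_enc),
                 dropout = x$config$dropout,
                 final_loss = if (length(x$fine_tune_loss) > 0) {
                   x$fine_tune_loss[length(x$fine_tune_loss)]
                 } else NA_real_)
}

#' @rdname harsdae-tidiers
#' @method tidy boost_kfold
#' @export
tidy.boost_kfold <- function(x, ...) {
  tibble::tibble(fold = seq_along(x$models),
                 train_size = x$train_sizes,
                 val_size = vapply(x$plan, function(f) length(f$val), integer(1)),
                 misjudged = x$misjudged_counts)
}

#' @rdname harsdae-tidiers
#' @method glance boost_kfold
#' @export
glance.boost_kfold <- function(x, ...) {
  tibble::tibble(k = length(x$models), n = attr(x$plan, "n"),
                 n_classes = length(x$levels),
                 total_misjudged = sum(x$misjudged_counts))
}

#' @rdname harsdae-tidiers
#' @method tidy har_eval
#' @export
tidy.har_eval <- function(x, ...) x$per_class

#' @rdname harsdae-tidiers
#' @method glance har_eval
#' @export
glance.har_eval <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, precision = x$precision,
                 recall = x$recall, f1 = x$f1,
                 n = sum(x$confusion), n_classes = nrow(x$confusion))
}

#' @rdname harsdae-tidiers
#' @method tidy har_divergence
#' @export
tidy.har_divergence <- function(x, ...) x$totals

#' @rdname harsdae-tidiers
#' @method tidy single_sdae
#' @export
tidy.single_sdae <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_history), loss = x$loss_history)
}
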