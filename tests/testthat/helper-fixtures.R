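# Shared fixtures, built in code at test time.

# Small labelled Gaussian-blob feature table (har_features layout).
toy_features <- function(n_per_class = 20, means = list(a = c(0, 0), b = c(5, 5)),
                         sd = 0.3, seed = 42) {
  withr::with_seed(seed, {
    feats <- do.call(rbind, lapply(means, function(m) {
      matrix(rnorm(n_per_class * length(m), mean = rep(m, each = n_per_class),
                   sd = sd), n_per_class)
    }))
    out <- tibble::tibble(
      window_id = seq_len(nrow(feats)),
      activity = rep(names(means), each = n_per_class))
    out$features <- feats
    class(out) <- c("har_features", class(out))
    out
  })
}

# Backend stubs for the boosting k-fold bookkeeping tests. Sample
# identity is carried in the (single) feature column: value = sample id.
# `truth` maps id -> true label.
oracle_backend <- function(truth) {
  function(X, y) {
    structure(list(truth = truth), class = "stub_oracle")
  }
}
predict.stub_oracle <- function(object, newdata, ...) {
  object$truth[round(newdata[, 1])]
}
registerS3method("predict", "stub_oracle", predict.stub_oracle)

# Misclassifies exactly the samples whose id is in `wrong_ids`.
erring_backend <- function(truth, wrong_ids, labels) {
  function(X, y) {
    structure(list(truth = truth, wrong_ids = wrong_ids, labels = labels),
              class = "stub_erring")
  }
}
predict.stub_erring <- function(object, newdata, ...) {
  ids <- round(newdata[, 1])
  pred <- object$truth[ids]
  flip <- ids %in% object$wrong_ids
  # predict the "next" class cyclically for designated error samples
  pred[flip] <- object$labels[(match(pred[flip], object$labels) %%
                                 length(object$labels)) + 1L]
  pred
}
registerS3method("predict", "stub_erring", predict.stub_erring)

# id-feature matrix for n samples
id_features <- function(n) matrix(seq_len(n), ncol = 1)

# Tiny synthetic dataset shared across test files (cheap: 2 s recordings).
tiny_dataset <- function(seed = 7, duration = 3, recordings_per_class = 4) {
  simulate_har_dataset(duration = duration,
                       recordings_per_class = recordings_per_class,
                       seed = seed)
}

# Write a minimal synthetic UCI-layout fixture; returns the root dir.
write_uci_fixture <- function(dir = withr::local_tempdir(.local_envir = parent.frame()),
                              n_windows = 6, seed = 5) {
  withr::with_seed(seed, {
    sig_dir <- file.path(dir, "train", "Inertial Signals")
    dir.create(sig_dir, recursive = TRUE, showWarnings = FALSE)
    for (s in c("body_acc", "body_gyro", "total_acc")) {
      for (a in c("x", "y", "z")) {
        m <- matrix(round(rnorm(n_windows * 128), 4), n_windows, 128)
        utils::write.table(m, file.path(sig_dir, sprintf("%s_%s_train.txt", s, a)),
                           row.names = FALSE, col.names = FALSE)
      }
    }
    writeLines(as.character(rep_len(1:3, n_windows)),
               file.path(dir, "train", "y_train.txt"))
    writeLines(c("1 WALKING", "2 SITTING", "3 STANDING"),
               file.path(dir, "activity_labels.txt"))
  })
  dir
}
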