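#' Model specification
#'
#' Describes one of the three model families. LDA and the linear-kernel SVM
#' consume the 217-feature matrix; the convolutional-LSTM consumes raw
#' 14 x 2560 windows.
#'
#' @param family "lda", "svm" or "clstm".
#' @param cost SVM cost parameter (default 1).
#' @param epochs,batch_size,lr CLSTM training epochs (default 30), minibatch
#'   size (default 32, capped at the training-set size) and Adam learning
#'   rate (default 1e-3).
#' @param seed Seed for stochastic training (CLSTM weight init and batching).
#' @return A list of class `eeg_model_spec` with an `input` field
#'   ("features" or "raw") implied by the family.
#' @export
model_spec <- function(family = c("lda", "svm", "clstm"), cost = 1,
                       epochs = 30, batch_size = 32, lr = 1e-3, seed = 0) {
  family <- match.arg(family)
  structure(list(
    family = family, cost = cost, epochs = epochs, batch_size = batch_size,
    lr = lr, seed = seed,
    input = if (family == "clstm") "raw" else "features"
  ), class = "eeg_model_spec")
}

.meta_cols <- c("participant_id", "movie_id", "window_index",
                "valence", "arousal", "valence_cont", "arousal_cont", "eeg")

# Feature matrix + binary label factor from a rows tibble.
.xy <- function(rows, target, feature_set = NULL) {
  cols <- feature_set %||% setdiff(names(rows), .meta_cols)
  x <- as.matrix(rows[, cols, drop = FALSE])
  y <- factor(rows[[target]], levels = c("low", "high"))
  list(x = x, y = y)
}

#' Train on one fold and predict the test rows
#'
#' For feature-mode families the feature columns are z-scored with means and
#' SDs fitted on the training rows only (zero-variance columns dropped);
#' LDA is fit with `MASS::lda` and the SVM with a linear kernel via
#' `e1071::svm`. For the CLSTM, raw windows are z-scored per channel with
#' training statistics and passed through the built-in network.
#'
#' @param spec An `eeg_model_spec`.
#' @param train,test Row tibbles: an `eeg_features` subset for LDA/SVM, a
#'   windows tibble (with `eeg` list-column) for the CLSTM.
#' @param target "valence" or "arousal".
#' @param feature_set Optional character vector restricting the feature
#'   columns used (LDA/SVM only).
#' @return Tibble with one row per test window: `truth`, `pred` (both
#'   "low"/"high") and a real-valued `score` (posterior probability or
#'   decision value for the positive class).
#' @export
fit_predict <- function(spec, train, test, target = "valence",
                        feature_set = NULL) {
  stopifnot(inherits(spec, "eeg_model_spec"))
  truth <- as.character(test[[target]])
  if (dplyr::n_distinct(train[[target]]) < 2) {
    rlang::abort("single-class training set")
  }
  if (spec$family == "clstm") {
    return(.fit_predict_clstm(spec, train, test, target, truth))
  }
  tr <- .xy(train, target, feature_set)
  te <- .xy(test, target, feature_set)
  if (!all(is.finite(tr$x)) || !all(is.finite(te$x))) {
    rlang::abort("non-finite feature values")
  }
  mu <- colMeans(tr$x)
  sd_ <- apply(tr$x, 2, stats::sd)
  keep <- sd_ > 0
  if (!any(keep)) rlang::abort("all features constant in training data")
  xs_tr <- sweep(sweep(tr$x[, keep, drop = FALSE], 2, mu[keep]),
                 2, sd_[keep], "/")
  xs_te <- sweep(sweep(te$x[, keep, drop = FALSE], 2, mu[keep]),
                 2, sd_[keep], "/")
  if (spec$family == "lda") {
    fit <- suppressWarnings(MASS::lda(xs_tr, tr$y))
    pr <- stats::predict(fit, xs_te)
    pred <- as.character(pr$class)
    score <- pr$posterior[, "high"]
  } else {
    fit <- e1071::svm(xs_tr, tr$y, kernel = "linear", cost = spec$cost,
                      scale = FALSE)
    pr <- stats::predict(fit, xs_te, decision.values = TRUE)
    pred <- as.character(pr)
    dv <- attr(pr, "decision.values")
    # orient the decision value toward the "high" class
    score <- if (grepl("^high", colnames(dv)[1])) dv[, 1] else -dv[, 1]
  }
  tibble::tibble(truth = truth, pred = pred, score = unname(score))
}

.fit_predict_clstm <- function(spec, train, test, target, truth) {
  xtr <- .stack_windows(train$eeg)
  xte <- .stack_windows(test$eeg)
  # per-channel z-scoring with training statistics
  mu <- apply(xtr, 3, mean)
  sd_ <- apply(xtr, 3, stats::sd)
  sd_[sd_ == 0] <- 1
  for (c_ in seq_along(mu)) {
    xtr[, , c_] <- (xtr[, , c_] - mu[c_]) / sd_[c_]
    xte[, , c_] <- (xte[, , c_] - mu[c_]) / sd_[c_]
  }
  y <- as.integer(train[[target]] == "high")
  net <- clstm_build(n_channels = dim(xtr)[3], n_samples = dim(xtr)[2],
                     seed = spec$seed)
  net <- clstm_train(net, xtr, y, epochs = spec$epochs,
                     batch_size = spec$batch_size, lr = spec$lr,
                     seed = spec$seed)
  p <- clstm_forward(net, xte)
  tibble::tibble(truth = truth,
                 pred = ifelse(p > 0.5, "high", "low"),
                 score = p)
}

# list of channels x samples matrices -> (batch, samples, channels) array
.stack_windows <- function(eeg_list) {
  b <- length(eeg_list)
  nch <- nrow(eeg_list[[1]])
  ns <- ncol(eeg_list[[1]])
  x <- array(0, c(b, ns, nch))
  for (i in seq_len(b)) x[i, , ] <- t(eeg_list[[i]])
  x
}
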