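#' Fold-averaged F1 of a feature set
#'
#' The wrapper objective: for each fold, fit the model on the training rows
#' restricted to `feature_set`, predict the test rows, and compute the
#' positive-class F1; the score is the unweighted mean over folds. Folds
#' whose training rows contain a single class are skipped with a warning;
#' if every fold is degenerate an error is raised.
#'
#' @param features An `eeg_features` tibble.
#' @param target "valence" or "arousal".
#' @param folds An `eeg_folds` tibble.
#' @param spec An `eeg_model_spec` (feature-mode family).
#' @param feature_set Character vector of feature column names.
#' @return Scalar mean F1.
#' @export
score_feature_set <- function(features, target, folds, spec, feature_set) {
  keys <- window_key(features)
  scores <- purrr::map_dbl(seq_len(nrow(folds)), function(i) {
    tr <- features[keys %in% folds$train[[i]], , drop = FALSE]
    te <- features[keys %in% folds$test[[i]], , drop = FALSE]
    if (dplyr::n_distinct(tr[[target]]) < 2) {
      rlang::warn(paste0("fold ", folds$fold_id[i],
                         ": single-class training set, skipped"))
      return(NA_real_)
    }
    pr <- fit_predict(spec, tr, te, target, feature_set)
    suppressWarnings(prf1(confusion(pr$pred, pr$truth))$f1)
  })
  if (all(is.na(scores))) rlang::abort("all folds degenerate")
  mean(scores, na.rm = TRUE)
}

.new_trace <- function(method, steps, candidates, target, spec_family) {
  trace <- dplyr::bind_rows(steps)
  scores <- trace$score
  best_idx <- which(scores == max(scores))
  # equal best scores: prefer the smaller active set
  best_idx <- best_idx[which.min(lengths(trace$set[best_idx]))]
  structure(trace, class = c("eeg_selection", class(trace)),
            method = method, candidates = candidates, target = target,
            model = spec_family,
            best_set = trace$set[[best_idx]],
            best_size = length(trace$set[[best_idx]]),
            best_score = trace$score[best_idx])
}

#' Sequential forward / backward wrapper feature selection
#'
#' Greedy wrapper search scored by [score_feature_set()]. `sfs()` starts
#' from the empty set and at each step adds the candidate whose inclusion
#' maximises the fold-averaged F1; `sbs()` starts from the full candidate
#' set and removes the feature whose exclusion leaves the highest score.
#' Ties break to the earliest candidate in registry order. The best set is
#' the step with the maximum score (smallest set among equals).
#'
#' @inheritParams score_feature_set
#' @param candidates Feature names to search over (default: all feature
#'   columns, in registry order).
#' @param max_steps Optional cap on the number of greedy steps (a tractable
#'   partial sweep; the full path runs to all candidates).
#' @return An `eeg_selection` tibble: one row per step with `step`, `action`,
#'   `feature`, `size`, `score`, `set` (list-column), plus attributes
#'   `method`, `best_set`, `best_size`, `best_score`.
#' @export
sfs <- function(features, target, folds, spec, candidates = NULL,
                max_steps = NULL) {
  candidates <- candidates %||% feature_names(features)
  if (length(candidates) < 2) rlang::abort("need at least 2 candidate features")
  n_steps <- min(max_steps %||% length(candidates), length(candidates))
  active <- character(0)
  steps <- vector("list", n_steps)
  for (s in seq_len(n_steps)) {
    pool <- setdiff(candidates, active)
    sc <- purrr::map_dbl(pool, function(f) {
      score_feature_set(features, target, folds, spec, c(active, f))
    })
    pick <- pool[which.max(sc)]
    active <- c(active, pick)
    steps[[s]] <- tibble::tibble(step = s, action = "add", feature = pick,
                                 size = length(active), score = max(sc),
                                 set = list(active))
  }
  .new_trace("SFS", steps, candidates, target, spec$family)
}

#' @rdname sfs
#' @export
sbs <- function(features, target, folds, spec, candidates = NULL,
                max_steps = NULL) {
  candidates <- candidates %||% feature_names(features)
  active <- candidates
  full_score <- score_feature_set(features, target, folds, spec, active)
  steps <- list(tibble::tibble(step = 1L, action = "start", feature = NA_character_,
                               size = length(active), score = full_score,
                               set = list(active)))
  n_steps <- min(max_steps %||% (length(candidates) - 1L),
                 length(candidates) - 1L)
  for (s in seq_len(n_steps)) {
    sc <- purrr::map_dbl(active, function(f) {
      score_feature_set(features, target, folds, spec, setdiff(active, f))
    })
    drop <- active[which.max(sc)]
    active <- setdiff(active, drop)
    steps[[s + 1L]] <- tibble::tibble(step = s + 1L, action = "remove",
                                      feature = drop, size = length(active),
                                      score = max(sc), set = list(active))
  }
  .new_trace("SBS", steps, candidates, target, spec$family)
}

#' Report the first k selected features
#'
#' For an SFS trace, the first `k` features in selection order and the score
#' using exactly those `k`; for SBS, the surviving set of size `k` (ordered
#' by registry order). The fraction is score(k) / best score of the trace.
#'
#' @param trace An `eeg_selection`.
#' @param k Set size to report.
#' @return List with `features`, `score`, `fraction`, `best_score`.
#' @export
top_k_report <- function(trace, k) {
  if (k < 1) rlang::abort("k must be >= 1")
  sizes <- trace$size
  row <- which(sizes == k)
  if (length(row) == 0) rlang::abort("no step of the trace has a set of size k")
  row <- row[1]
  feats <- if (attr(trace, "method") == "SFS") {
    trace$feature[seq_len(k)]
  } else trace$set[[row]]
  list(features = feats, score = trace$score[row],
       fraction = trace$score[row] / attr(trace, "best_score"),
       best_score = attr(trace, "best_score"))
}

#' @export
print.eeg_selection <- function(x, ...) {
  cat("<eeg_selection> ", attr(x, "method"), " over ",
      length(attr(x, "candidates")), " candidates (", attr(x, "model"),
      ", ", attr(x, "target"), "): best F1 = ",
      round(attr(x, "best_score"), 4), " with ", attr(x, "best_size"),
      " features\n", sep = "")
  NextMethod()
}

#' Tidy a selection trace
#'
#' @param x An `eeg_selection`.
#' @param ... Unused.
#' @return A plain tibble of the greedy path (step, action, feature, size,
#'   score).
#' @export
tidy.eeg_selection <- function(x, ...) {
  tibble::as_tibble(x[, c("step", "action", "feature", "size", "score")])
}

#' Selection-profile plot (score vs feature-set size)
#'
#' @param object An `eeg_selection`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eeg_selection <- function(object, ...) {
  df <- tibble::tibble(size = object$size, score = object$score)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size, y = .data$score)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = attr(object, "best_size"),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "Number of features", y = "Fold-averaged F1",
                  title = paste0(attr(object, "method"), " selection profile (",
                                 attr(object, "target"), ", ",
                                 attr(object, "model"), ")")) +
    ggplot2::theme_minimal()
}
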