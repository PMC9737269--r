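#' Confusion counts for binary affect labels
#'
#' @param pred,truth Character/factor vectors of "low"/"high" labels.
#' @param positive The positive class (default "high").
#' @return Named list `TP`, `FP`, `FN`, `TN` of class `eeg_confusion`.
#' @examples
#' confusion(c("high", "low", "high"), c("high", "high", "low"))
#' @export
confusion <- function(pred, truth, positive = "high") {
  stopifnot(length(pred) == length(truth))
  pred <- as.character(pred); truth <- as.character(truth)
  structure(list(
    TP = sum(pred == positive & truth == positive),
    FP = sum(pred == positive & truth != positive),
    FN = sum(pred != positive & truth == positive),
    TN = sum(pred != positive & truth != positive)
  ), class = "eeg_confusion")
}

#' Precision, recall and F1 from confusion counts
#'
#' Precision = TP / (TP + FP), recall = TP / (TP + FN), F1 = harmonic mean of
#' the two. Zero-denominator cases (no predicted or no true positives) return
#' 0 with a warning — the convention needed for extreme-imbalance folds.
#'
#' @param counts An `eeg_confusion` or a list with `TP`, `FP`, `FN`.
#' @return One-row tibble `precision`, `recall`, `f1`.
#' @examples
#' prf1(list(TP = 3, FP = 1, FN = 2))
#' @export
prf1 <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN
  prec <- if (tp + fp == 0) {
    rlang::warn("no positive predictions; precision set to 0")
    0
  } else tp / (tp + fp)
  rec <- if (tp + fn == 0) {
    rlang::warn("no positive instances; recall set to 0")
    0
  } else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  tibble::tibble(precision = prec, recall = rec, f1 = f1)
}

#' Compare fold-score distributions across configurations
#'
#' The significance procedure used for result tables: each configuration's
#' per-fold F1 scores are first tested for normality with a one-sample
#' Kolmogorov-Smirnov test on standardized scores (the mean and SD are
#' estimated from the same scores, which makes the test approximate — noted
#' in the report), then the configurations are compared with the
#' non-parametric Kruskal-Wallis H-test.
#'
#' @param scores A named list of numeric per-fold score vectors, or a list of
#'   `eeg_eval` objects (fold F1 vectors are taken from each).
#' @param alpha Significance level (default 0.05).
#' @return A list of class `eeg_comparison`: `normality` tibble (one row per
#'   group: KS statistic, p, `normal` verdict at `alpha`), `kruskal` (H
#'   statistic, df, p), `significant`, `alpha`.
#' @export
compare_configs <- function(scores, alpha = 0.05) {
  if (all(vapply(scores, inherits, TRUE, what = "eeg_eval"))) {
    nm <- names(scores)
    scores <- lapply(scores, function(e) e$folds$f1)
    names(scores) <- nm
  }
  if (length(scores) < 2) rlang::abort("need at least 2 result groups")
  if (is.null(names(scores)) || any(names(scores) == "")) {
    names(scores) <- paste0("group", seq_along(scores))
  }
  if (any(vapply(scores, length, 1L) < 2)) {
    rlang::abort("every group needs at least 2 fold scores")
  }
  normality <- purrr::imap_dfr(scores, function(x, nm) {
    s <- stats::sd(x)
    if (s == 0) {
      return(tibble::tibble(group = nm, ks_statistic = NA_real_,
                            ks_p = NA_real_, normal = FALSE))
    }
    z <- (x - mean(x)) / s
    kt <- suppressWarnings(stats::ks.test(z, "pnorm"))
    tibble::tibble(group = nm, ks_statistic = unname(kt$statistic),
                   ks_p = kt$p.value, normal = kt$p.value >= alpha)
  })
  flat <- unlist(scores, use.names = FALSE)
  grp <- factor(rep(names(scores), vapply(scores, length, 1L)))
  if (stats::var(flat) == 0) {
    kw <- list(statistic = 0, parameter = length(scores) - 1, p.value = 1)
  } else {
    kwt <- stats::kruskal.test(flat, grp)
    kw <- list(statistic = unname(kwt$statistic),
               parameter = unname(kwt$parameter), p.value = kwt$p.value)
  }
  structure(list(
    normality = normality,
    kruskal = tibble::tibble(H = kw$statistic, df = kw$parameter,
                             p = kw$p.value),
    significant = kw$p.value < alpha,
    alpha = alpha
  ), class = "eeg_comparison")
}

#' @export
print.eeg_comparison <- function(x, ...) {
  cat("<eeg_comparison>\n")
  print(x$normality)
  cat(sprintf("Kruskal-Wallis H = %.4f (df = %d), p = %.4g; %ssignificant at alpha = %g\n",
              x$kruskal$H, x$kruskal$df, x$kruskal$p,
              if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}
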