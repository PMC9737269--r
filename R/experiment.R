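.frameworks <- c("LOPO", "LOMO_INTER", "LOMO_WITHIN", "LOPMO")

.build_folds <- function(cohort, framework, retained, target) {
  folds <- switch(framework,
    LOPO = lopo_folds(cohort, participants = retained),
    LOMO_INTER = lomo_inter_folds(cohort, participants = retained),
    LOMO_WITHIN = purrr::map_dfr(retained, function(p) {
      lomo_within_folds(cohort, p, participants = retained, target = target)
    }),
    LOPMO = lopmo_folds(cohort, participants = retained)
  )
  if (framework == "LOMO_WITHIN") class(folds) <- c("eeg_folds", class(folds))
  check_folds(folds)
}

# Stratified k-fold on training rows, for nested selection.
.inner_folds <- function(rows, target, k = 3, seed = 0) {
  set.seed(seed)
  keys <- window_key(rows)
  y <- rows[[target]]
  assign_fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    assign_fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  rows_list <- purrr::map(seq_len(k), function(i) {
    tibble::tibble(fold_id = paste0("inner", i),
                   test_participant = NA, test_movie = NA,
                   train = list(keys[assign_fold != i]),
                   test = list(keys[assign_fold == i]))
  })
  out <- dplyr::bind_rows(rows_list)
  out$framework <- "INNER"
  class(out) <- c("eeg_folds", class(out))
  out
}

.fold_f1 <- function(pred, truth, f1_mode) {
  if (f1_mode == "positive") {
    suppressWarnings(prf1(confusion(pred, truth))$f1)
  } else {
    mean(c(suppressWarnings(prf1(confusion(pred, truth, "high"))$f1),
           suppressWarnings(prf1(confusion(pred, truth, "low"))$f1)))
  }
}

#' Run one cross-validated emotion-recognition experiment
#'
#' Orchestrates the full evaluation for one configuration: participant
#' exclusions, fold construction with leakage assertions, optional wrapper
#' feature selection, per-fold model fitting, and fold-level
#' precision/recall/F1.
#'
#' @param cohort An `eeg_cohort`.
#' @param framework "LOPO", "LOMO_INTER", "LOMO_WITHIN" or "LOPMO".
#' @param target "valence" or "arousal".
#' @param spec An `eeg_model_spec`. The CLSTM consumes raw windows and does
#'   not combine with wrapper selection.
#' @param selection "none", "sfs" or "sbs".
#' @param features Precomputed `eeg_features` (computed from the cohort when
#'   NULL and the model is feature-based).
#' @param feature_subset Optional candidate feature names (a tractable cap
#'   on the wrapper search and on the fitted feature set).
#' @param min_minority LOMO-Within minority-count exclusion threshold.
#' @param selection_mode "outer" scores selection on the same folds used for
#'   reporting (the protocol implied by score-vs-feature-count selection
#'   profiles; optimistically biased); "nested" reruns selection inside each
#'   training fold on inner stratified splits.
#' @param max_steps Cap on greedy selection steps.
#' @param f1_mode "positive" (F1 of the "high" class) or "macro" (mean of
#'   the two one-vs-rest F1 scores); recorded in the result metadata.
#' @return An object of class `eeg_eval`: list with `folds` (per-fold
#'   confusion counts and metrics), `summary` (unweighted fold means),
#'   `config`, and the selection `trace` when selection ran in outer mode.
#' @export
run_experiment <- function(cohort, framework = .frameworks,
                           target = c("valence", "arousal"),
                           spec = model_spec("lda"),
                           selection = c("none", "sfs", "sbs"),
                           features = NULL, feature_subset = NULL,
                           min_minority = 10,
                           selection_mode = c("outer", "nested"),
                           max_steps = NULL,
                           f1_mode = c("positive", "macro")) {
  framework <- match.arg(framework)
  target <- match.arg(target)
  selection <- match.arg(selection)
  selection_mode <- match.arg(selection_mode)
  f1_mode <- match.arg(f1_mode)
  if (spec$family == "clstm" && selection != "none") {
    rlang::abort("wrapper selection applies to feature-based models only")
  }
  retained <- apply_exclusions(cohort, framework, target, min_minority)
  folds <- .build_folds(cohort, framework, retained, target)

  if (spec$family == "clstm") {
    rows <- cohort$windows
  } else {
    rows <- features %||% extract_features(cohort)
  }
  keys <- window_key(rows)

  trace <- NULL
  fit_sets <- rep(list(feature_subset), nrow(folds))
  if (selection != "none") {
    sel_fun <- if (selection == "sfs") sfs else sbs
    if (selection_mode == "outer") {
      trace <- sel_fun(rows, target, folds, spec,
                       candidates = feature_subset, max_steps = max_steps)
      fit_sets <- rep(list(attr(trace, "best_set")), nrow(folds))
    } else {
      fit_sets <- purrr::map(seq_len(nrow(folds)), function(i) {
        tr_rows <- rows[keys %in% folds$train[[i]], , drop = FALSE]
        inner <- .inner_folds(tr_rows, target, seed = spec$seed + i)
        tr <- sel_fun(tr_rows, target, inner, spec,
                      candidates = feature_subset, max_steps = max_steps)
        attr(tr, "best_set")
      })
    }
  }

  fold_rows <- purrr::map_dfr(seq_len(nrow(folds)), function(i) {
    out <- tibble::tibble(
      framework = framework, fold_id = folds$fold_id[i],
      test_participant = folds$test_participant[i],
      test_movie = folds$test_movie[i],
      n_train = length(folds$train[[i]]), n_test = length(folds$test[[i]]),
      TP = NA_integer_, FP = NA_integer_, FN = NA_integer_, TN = NA_integer_,
      precision = NA_real_, recall = NA_real_, f1 = NA_real_
    )
    tr <- rows[keys %in% folds$train[[i]], , drop = FALSE]
    te <- rows[keys %in% folds$test[[i]], , drop = FALSE]
    if (nrow(te) == 0 || dplyr::n_distinct(tr[[target]]) < 2) {
      rlang::warn(paste0("fold ", folds$fold_id[i],
                         ": degenerate (single-class train or empty test), skipped"))
      return(out)
    }
    pr <- fit_predict(spec, tr, te, target, fit_sets[[i]])
    cm <- confusion(pr$pred, pr$truth)
    met <- suppressWarnings(prf1(cm))
    out$TP <- cm$TP; out$FP <- cm$FP; out$FN <- cm$FN; out$TN <- cm$TN
    out$precision <- met$precision; out$recall <- met$recall
    out$f1 <- .fold_f1(pr$pred, pr$truth, f1_mode)
    out
  })

  n_features <- if (spec$family == "clstm") {
    NA_integer_
  } else if (selection != "none" && selection_mode == "outer") {
    length(fit_sets[[1]])
  } else if (!is.null(feature_subset)) {
    length(feature_subset)
  } else length(feature_names(rows))

  summary <- tibble::tibble(
    framework = framework, target = target, model = spec$family,
    selection = selection, f1_mode = f1_mode,
    n_folds = nrow(fold_rows), n_folds_scored = sum(!is.na(fold_rows$f1)),
    n_features = n_features,
    precision = mean(fold_rows$precision, na.rm = TRUE),
    recall = mean(fold_rows$recall, na.rm = TRUE),
    f1 = mean(fold_rows$f1, na.rm = TRUE)
  )
  structure(list(
    folds = fold_rows, summary = summary,
    config = list(framework = framework, target = target,
                  model = spec$family, spec = spec, selection = selection,
                  selection_mode = selection_mode, f1_mode = f1_mode,
                  min_minority = min_minority, retained = retained,
                  feature_subset = feature_subset, max_steps = max_steps),
    trace = trace
  ), class = "eeg_eval")
}

#' @export
print.eeg_eval <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<eeg_eval> %s | %s | %s | selection %s: mean F1 = %.4f over %d folds (%d features)\n",
              s$framework, s$target, s$model, s$selection, s$f1,
              s$n_folds_scored, s$n_features))
  invisible(x)
}

#' Tidy per-fold evaluation results
#'
#' @param x An `eeg_eval`.
#' @param ... Unused.
#' @return Tibble with one row per fold: confusion counts, precision,
#'   recall, F1.
#' @export
tidy.eeg_eval <- function(x, ...) x$folds

#' One-row evaluation summary
#'
#' @param x An `eeg_eval`.
#' @param ... Unused.
#' @return One-row tibble of fold-averaged metrics and configuration.
#' @export
glance.eeg_eval <- function(x, ...) x$summary

#' Per-fold F1 plot for an evaluation
#'
#' @param object An `eeg_eval`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eeg_eval <- function(object, ...) {
  df <- dplyr::filter(object$folds, !is.na(.data$f1))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fold_id, y = .data$f1)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$summary$f1, linetype = "dashed") +
    ggplot2::labs(x = "Fold", y = "F1",
                  title = sprintf("%s / %s / %s: mean F1 = %.3f",
                                  object$summary$framework,
                                  object$summary$target,
                                  object$summary$model, object$summary$f1)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Run a configured grid of experiments
#'
#' Executes extract -> (select) -> evaluate over the full grid of frameworks
#' x targets x models x selection methods, in that fixed order, and writes
#' per-cell fold tables, selection traces, a combined summary and a manifest
#' (seeds, parameters, package version, failures) into `out_dir`.
#'
#' @param config A list with elements `preset` (generator preset name) or
#'   `cohort` (an `eeg_cohort`), `frameworks`, `targets`, `models`
#'   (families), `selection` (methods), `seed`, and optionally
#'   `feature_subset`, `max_steps`, `min_minority`, `clstm` (list of epochs/
#'   batch_size/lr overrides).
#' @param out_dir Output directory.
#' @return Invisibly, a list with the manifest and the `eeg_eval` objects.
#' @export
run_pipeline <- function(config, out_dir) {
  frameworks <- config$frameworks %||% "LOPO"
  targets <- config$targets %||% "valence"
  models <- config$models %||% "lda"
  selections <- config$selection %||% "none"
  seed <- config$seed %||% 1
  bad <- setdiff(frameworks, .frameworks)
  if (length(bad)) rlang::abort(paste0("unknown framework: ", bad[1]))
  bad <- setdiff(models, c("lda", "svm", "clstm"))
  if (length(bad)) rlang::abort(paste0("unknown model: ", bad[1]))
  bad <- setdiff(selections, c("none", "sfs", "sbs"))
  if (length(bad)) rlang::abort(paste0("unknown selection method: ", bad[1]))

  dir.create(file.path(out_dir, "results"), showWarnings = FALSE,
             recursive = TRUE)
  dir.create(file.path(out_dir, "traces"), showWarnings = FALSE)
  cohort <- config$cohort %||%
    generate_cohort(cohort_preset(config$preset %||% "mini", seed = seed))
  features <- if (any(models != "clstm")) extract_features(cohort) else NULL

  evals <- list(); failures <- list()
  for (fw in frameworks) for (tg in targets) for (md in models) {
    for (sl in (if (md == "clstm") "none" else selections)) {
      cell <- paste(fw, tg, md, sl, sep = "_")
      res <- tryCatch({
        cl <- config$clstm %||% list()
        sp <- model_spec(md, seed = seed,
                         epochs = cl$epochs %||% 30,
                         batch_size = cl$batch_size %||% 32,
                         lr = cl$lr %||% 1e-3)
        ev <- run_experiment(cohort, fw, tg, sp, selection = sl,
                             features = features,
                             feature_subset = config$feature_subset,
                             min_minority = config$min_minority %||% 10,
                             max_steps = config$max_steps)
        readr::write_csv(ev$folds,
                         file.path(out_dir, "results", paste0(cell, ".csv")),
                         progress = FALSE)
        if (!is.null(ev$trace)) {
          readr::write_csv(tidy(ev$trace),
                           file.path(out_dir, "traces", paste0(cell, ".csv")),
                           progress = FALSE)
        }
        ev
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[cell]] <- conditionMessage(res)
      } else {
        evals[[cell]] <- res
      }
    }
  }
  summary <- purrr::map_dfr(evals, glance)
  readr::write_csv(summary, file.path(out_dir, "summary.csv"),
                   progress = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("eegaffect")),
    seed = seed, frameworks = frameworks, targets = targets,
    models = models, selection = selections,
    preset = config$preset %||% NA,
    feature_subset = config$feature_subset, max_steps = config$max_steps,
    cells = names(evals), failures = failures
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(manifest = manifest, evals = evals))
}
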