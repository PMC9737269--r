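# Shared tiny cohort + features for the orchestration tests.
tiny_co <- generate_cohort(cohort_preset("tiny", seed = 90))
tiny_f <- extract_features(tiny_co)
gamma_set <- grep("PSD gamma", feature_names(tiny_f), value = TRUE)

test_that("experiments rerun identically from the same inputs", {
  e1 <- suppressWarnings(run_experiment(tiny_co, "LOPO", "valence",
                                        model_spec("svm"), features = tiny_f))
  e2 <- suppressWarnings(run_experiment(tiny_co, "LOPO", "valence",
                                        model_spec("svm"), features = tiny_f))
  expect_identical(e1$folds, e2$folds)
  expect_identical(e1$summary, e2$summary)
})

test_that("a strong planted effect is recovered under LOPO", {
  ev <- suppressWarnings(run_experiment(tiny_co, "LOPO", "valence",
                                        model_spec("svm"), features = tiny_f))
  expect_gt(ev$summary$f1, 0.9)
  expect_identical(ev$summary$n_folds, 3L)
})

test_that("outer-mode selection attaches a trace and reports its set size", {
  sub <- c("T7 PSD gamma", "T8 PSD gamma", "O1 PSD theta", "F3 HFD")
  ev <- suppressWarnings(run_experiment(tiny_co, "LOPO", "valence",
                                        model_spec("lda"), selection = "sfs",
                                        features = tiny_f,
                                        feature_subset = sub, max_steps = 3))
  expect_s3_class(ev$trace, "eeg_selection")
  expect_identical(ev$summary$n_features, attr(ev$trace, "best_size"))
  expect_true(all(attr(ev$trace, "best_set") %in% sub))
  expect_lte(ev$summary$n_features, 3L)
})

test_that("nested selection runs per fold without an outer trace", {
  sub <- c("T7 PSD gamma", "T8 PSD gamma", "O1 PSD theta")
  ev <- suppressWarnings(run_experiment(tiny_co, "LOMO_INTER", "valence",
                                        model_spec("lda"), selection = "sfs",
                                        features = tiny_f, feature_subset = sub,
                                        max_steps = 2,
                                        selection_mode = "nested"))
  expect_null(ev$trace)
  expect_identical(ev$config$selection_mode, "nested")
  expect_true(all(is.finite(ev$summary$f1)))
})

test_that("the CLSTM path rejects wrapper selection", {
  expect_error(run_experiment(tiny_co, "LOPO", "valence",
                              model_spec("clstm"), selection = "sfs"),
               "feature-based")
})

test_that("macro and positive-class F1 modes are both reported", {
  ev_p <- suppressWarnings(run_experiment(tiny_co, "LOPO", "valence",
                                          model_spec("lda"), features = tiny_f,
                                          feature_subset = gamma_set))
  ev_m <- suppressWarnings(run_experiment(tiny_co, "LOPO", "valence",
                                          model_spec("lda"), features = tiny_f,
                                          feature_subset = gamma_set,
                                          f1_mode = "macro"))
  expect_identical(ev_p$summary$f1_mode, "positive")
  expect_identical(ev_m$summary$f1_mode, "macro")
  expect_true(is.finite(ev_m$summary$f1))
})

test_that("tidy, glance and autoplot expose the evaluation", {
  ev <- suppressWarnings(run_experiment(tiny_co, "LOPO", "valence",
                                        model_spec("lda"), features = tiny_f,
                                        feature_subset = gamma_set))
  td <- tidy(ev)
  expect_true(all(c("fold_id", "TP", "f1") %in% names(td)))
  gl <- glance(ev)
  expect_identical(nrow(gl), 1L)
  expect_s3_class(autoplot(ev), "ggplot")
  tr <- suppressWarnings(sfs(tiny_f, "valence", lopo_folds(tiny_co),
                             model_spec("lda"),
                             candidates = gamma_set[1:3], max_steps = 2))
  expect_s3_class(autoplot(tr), "ggplot")
  expect_identical(nrow(tidy(tr)), 2L)
})

test_that("generalization degrades from LOPO to LOPMO on nuisance-laden cohorts", {
  diffs <- sapply(1:10, function(s) {
    cfg <- generator_config(
      n_participants = 4, movie_durations = rep(200, 3),
      stationary_valence = rep(0.5, 3), stationary_arousal = rep(0.5, 3),
      persistence = 0.4,
      effects = tibble::tibble(target = "valence", channel = c("T7", "T8"),
                               band = "gamma", shift = 1),
      slope_effects = tibble::tibble(target = character(),
                                     channel = character(), shift = numeric()),
      participant_sd = 0.3, movie_sd = 0.25, flip_prob = 0.05, seed = 300 + s
    )
    co <- generate_cohort(cfg)
    f <- extract_features(co)
    sub <- grep("PSD gamma|HFD", feature_names(f), value = TRUE)
    lopo <- suppressWarnings(run_experiment(co, "LOPO", "valence",
                                            model_spec("lda"), features = f,
                                            feature_subset = sub))
    lopmo <- suppressWarnings(run_experiment(co, "LOPMO", "valence",
                                             model_spec("lda"), features = f,
                                             feature_subset = sub))
    lopo$summary$f1 - lopmo$summary$f1
  })
  se <- stats::sd(diffs) / sqrt(length(diffs))
  expect_gte(mean(diffs), -se)
})

test_that("the pipeline writes tables, traces and a manifest deterministically", {
  cfgrun <- list(cohort = tiny_co, frameworks = c("LOPO", "LOMO_INTER"),
                 targets = "valence", models = "lda", selection = "none",
                 feature_subset = gamma_set, seed = 4)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- suppressWarnings(run_pipeline(cfgrun, d1))
  r2 <- suppressWarnings(run_pipeline(cfgrun, d2))
  expect_length(r1$evals, 2)
  expect_true(file.exists(file.path(d1, "summary.csv")))
  expect_true(file.exists(file.path(d1, "manifest.json")))
  expect_identical(readLines(file.path(d1, "summary.csv")),
                   readLines(file.path(d2, "summary.csv")))
  expect_length(r1$manifest$failures, 0)
})

test_that("invalid pipeline configurations fail before any compute", {
  expect_error(run_pipeline(list(cohort = tiny_co, frameworks = "LOSO"),
                            withr::local_tempdir()), "unknown framework")
  expect_error(run_pipeline(list(cohort = tiny_co, models = "cnn"),
                            withr::local_tempdir()), "unknown model")
  expect_error(run_pipeline(list(cohort = tiny_co, selection = "mrmr"),
                            withr::local_tempdir()), "unknown selection")
})
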