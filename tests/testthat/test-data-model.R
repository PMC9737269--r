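make_ann <- function(n_periods, p = 1L, m = 1L, n_annotators = 3,
                     vfun = function(k) 0.5, afun = function(k) -0.5) {
  tidyr::expand_grid(period_index = seq_len(n_periods),
                     annotator_id = seq_len(n_annotators)) |>
    dplyr::mutate(participant_id = p, movie_id = m,
                  valence = vfun(period_index), arousal = afun(period_index))
}

test_that("label combination averages annotators and thresholds at zero", {
  ann <- tibble::tibble(participant_id = 1, movie_id = 1, period_index = 1,
                        annotator_id = 1:3,
                        valence = c(-0.2, -0.4, -0.1),
                        arousal = c(0.5, 0.5, 0.5))
  lb <- binarize_labels(ann)
  expect_equal(lb$valence_cont, mean(c(-0.2, -0.4, -0.1)))
  expect_identical(lb$valence, "low")
  expect_identical(lb$arousal, "high")

  ann2 <- dplyr::mutate(ann, valence = c(0.6, -0.3, 0))
  lb2 <- binarize_labels(ann2)
  expect_equal(lb2$valence_cont, 0.1)
  expect_identical(lb2$valence, "high")

  # exact zero resolves to low
  ann0 <- dplyr::mutate(ann, valence = c(0.3, -0.3, 0))
  expect_identical(binarize_labels(ann0)$valence, "low")

  # missing single-annotator entries drop out of the mean
  annm <- dplyr::mutate(ann, valence = c(0.4, NA, 0.2))
  expect_equal(binarize_labels(annm)$valence_cont, 0.3)

  expect_error(binarize_labels(ann[0, ]), "empty")
})

test_that("majority vote binarization differs from the mean when votes split", {
  ann <- tibble::tibble(participant_id = 1, movie_id = 1, period_index = 1,
                        annotator_id = 1:3,
                        valence = c(0.9, -0.1, -0.1),
                        arousal = c(0.9, -0.1, -0.1))
  expect_identical(binarize_labels(ann, "mean")$valence, "high")     # mean 0.233
  expect_identical(binarize_labels(ann, "majority")$valence, "low")  # 1 of 3 votes
})

test_that("binarization is sign-equivariant away from zero", {
  set.seed(20)
  ann <- make_ann(15, vfun = function(k) runif(length(k), -1, 1),
                  afun = function(k) runif(length(k), -1, 1))
  ann$valence[abs(ann$valence) < 0.05] <- 0.1
  neg <- dplyr::mutate(ann, valence = -valence, arousal = -arousal)
  l1 <- binarize_labels(ann)
  l2 <- binarize_labels(neg)
  nonzero <- abs(l1$valence_cont) > 1e-9
  expect_true(all(l1$valence[nonzero] != l2$valence[nonzero]))
})

test_that("segmentation drops the first and last periods and aligns boundaries", {
  layout <- channel_layout()
  for (np in c(70L, 3L)) {
    eeg <- matrix(seq_len(14 * np * 2560), 14)
    w <- segment_movie(eeg, make_ann(np), layout)
    expect_identical(nrow(w), np - 2L)
  }
  # 14:06 movie = 846 s -> 42 full annotation periods -> 40 windows, with
  # window k holding samples [k*2560+1, (k+1)*2560] of the source (0-based
  # period k); verified by brute-force boundary enumeration
  np <- floor(846 / 20)
  expect_identical(np, 42)
  eeg <- matrix(0, 14, 846 * 128)
  eeg[1, ] <- seq_len(846 * 128)
  w <- segment_movie(eeg, make_ann(np), layout)
  expect_identical(nrow(w), 40L)
  for (i in seq_len(nrow(w))) {
    k <- w$window_index[i]  # source period, 1-based
    expect_identical(w$eeg[[i]][1, 1], (k - 1) * 2560 + 1)
    expect_identical(w$eeg[[i]][1, 2560], k * 2560)
  }
  expect_identical(w$window_index, 2:41)
})

test_that("segmentation rejects misaligned or invalid inputs", {
  layout <- channel_layout()
  expect_error(segment_movie(matrix(0, 14, 2560 * 2), make_ann(2), layout),
               "at least 3")
  expect_error(segment_movie(matrix(0, 14, 2560 * 2), make_ann(6), layout),
               "disagree")
  bad <- matrix(0, 14, 2560 * 5); bad[3, 7] <- NA
  expect_error(segment_movie(bad, make_ann(5), layout), "non-finite")
  expect_error(segment_movie(matrix(0, 10, 2560 * 5), make_ann(5), layout),
               "channel count")
})

test_that("exclusion arithmetic reproduces the reference cohort sizes", {
  cohort <- make_roster_cohort(paper_valence_sparse, paper_arousal_sparse)
  expect_length(apply_exclusions(cohort, "LOPO"), 37)
  expect_length(apply_exclusions(cohort, "LOMO_INTER"), 37)
  expect_length(apply_exclusions(cohort, "LOPMO"), 34)
  expect_length(apply_exclusions(cohort, "LOMO_WITHIN", "valence"), 26)
  expect_length(apply_exclusions(cohort, "LOMO_WITHIN", "arousal"), 19)
  expect_false(any(c(8, 24, 28) %in% apply_exclusions(cohort, "LOPO")))
  expect_false(any(c(17, 18, 22) %in% apply_exclusions(cohort, "LOPMO")))
})

test_that("exclusion is monotone in the minority threshold", {
  cohort <- make_roster_cohort(paper_valence_sparse, paper_arousal_sparse)
  prev <- apply_exclusions(cohort, "LOMO_WITHIN", "valence", min_minority = 1)
  for (mm in c(3, 5, 10, 30)) {
    cur <- apply_exclusions(cohort, "LOMO_WITHIN", "valence", min_minority = mm)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
  # a participant with 9 minority windows is excluded at the default 10
  expect_false(20 %in% apply_exclusions(cohort, "LOMO_WITHIN", "valence"))
})

test_that("a cohort round-trips through the plain-text container bit-for-bit", {
  cfg <- generator_config(n_participants = 2, movie_durations = rep(80, 2),
                          stationary_valence = c(0.5, 0.5),
                          stationary_arousal = c(0.5, 0.5),
                          effects = tibble::tibble(target = character(),
                                                   channel = character(),
                                                   band = character(),
                                                   shift = numeric()),
                          slope_effects = tibble::tibble(target = character(),
                                                         channel = character(),
                                                         shift = numeric()),
                          seed = 21)
  cohort <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  expect_identical(back$layout$names, cohort$layout$names)
  expect_equal(as.data.frame(back$roster), as.data.frame(cohort$roster))
  expect_identical(back$windows$valence, cohort$windows$valence)
  expect_identical(back$windows$valence_cont, cohort$windows$valence_cont)
  for (i in seq_len(nrow(cohort$windows))) {
    expect_identical(back$windows$eeg[[i]], cohort$windows$eeg[[i]])
  }
})

test_that("annotation CSVs round-trip through the readers", {
  ann <- make_ann(5)[, c("participant_id", "movie_id", "period_index",
                         "annotator_id", "valence", "arousal")]
  ann <- dplyr::mutate(ann, dplyr::across(
    c("participant_id", "movie_id", "period_index", "annotator_id"),
    as.integer))
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotations(ann, path)
  expect_identical(as.data.frame(read_annotations(path)), as.data.frame(ann))
})
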