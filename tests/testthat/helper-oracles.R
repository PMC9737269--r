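# Independent oracles and fixture builders, deliberately coded as plain
# loops so they share no code path with the package implementation.

naive_band_logpower <- function(freq, power, f_low, f_high) {
  s <- 0
  for (i in seq_along(freq)) {
    if (freq[i] >= f_low && freq[i] <= f_high) s <- s + power[i]
  }
  log(s / (f_high - f_low))
}

naive_confusion <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == "high" && truth[i] == "high") tp <- tp + 1L
    if (pred[i] == "high" && truth[i] == "low") fp <- fp + 1L
    if (pred[i] == "low" && truth[i] == "high") fn <- fn + 1L
    if (pred[i] == "low" && truth[i] == "low") tn <- tn + 1L
  }
  list(TP = tp, FP = fp, FN = fn, TN = tn)
}

# Kruskal-Wallis H from explicit rank sums (no tie correction; use
# continuous data).
naive_kruskal_h <- function(groups) {
  all_v <- unlist(groups)
  r <- rank(all_v)
  n <- length(all_v)
  h <- 0
  offset <- 0
  for (g in groups) {
    rg <- r[(offset + 1):(offset + length(g))]
    h <- h + sum(rg)^2 / length(g)
    offset <- offset + length(g)
  }
  12 / (n * (n + 1)) * h - 3 * (n + 1)
}

# Fold-averaged F1 of a feature set, coded independently of
# score_feature_set (explicit loops, naive confusion counting).
naive_set_score <- function(features, target, folds, spec, fset) {
  keys <- paste(features$participant_id, features$movie_id,
                features$window_index, sep = ":")
  f1s <- c()
  for (i in seq_len(nrow(folds))) {
    tr <- features[keys %in% folds$train[[i]], ]
    te <- features[keys %in% folds$test[[i]], ]
    pr <- fit_predict(spec, tr, te, target, fset)
    cm <- naive_confusion(pr$pred, pr$truth)
    prec <- if (cm$TP + cm$FP == 0) 0 else cm$TP / (cm$TP + cm$FP)
    rec <- if (cm$TP + cm$FN == 0) 0 else cm$TP / (cm$TP + cm$FN)
    f1s <- c(f1s, if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec))
  }
  mean(f1s)
}

naive_sfs <- function(features, target, folds, spec, candidates) {
  active <- character(0)
  path <- list()
  for (s in seq_along(candidates)) {
    pool <- setdiff(candidates, active)
    best <- -Inf; pick <- NULL
    for (f in pool) {
      sc <- naive_set_score(features, target, folds, spec, c(active, f))
      if (sc > best) { best <- sc; pick <- f }
    }
    active <- c(active, pick)
    path[[s]] <- list(feature = pick, score = best, set = active)
  }
  path
}

naive_sbs <- function(features, target, folds, spec, candidates) {
  active <- candidates
  path <- list(list(feature = NA, score = naive_set_score(
    features, target, folds, spec, active), set = active))
  while (length(active) > 1) {
    best <- -Inf; drop <- NULL
    for (f in active) {
      sc <- naive_set_score(features, target, folds, spec, setdiff(active, f))
      if (sc > best) { best <- sc; drop <- f }
    }
    active <- setdiff(active, drop)
    path[[length(path) + 1]] <- list(feature = drop, score = best, set = active)
  }
  path
}

# Small feature-frame fixture shaped like an eeg_features tibble: two
# pseudo-participants (so lopo_folds gives 2 folds), labels balanced
# within each participant.
make_feature_frame <- function(feats, labels) {
  n <- length(labels)
  tibble::tibble(
    participant_id = rep(1:2, each = ceiling(n / 2))[seq_len(n)],
    movie_id = 1L,
    window_index = seq_len(n),
    valence = labels, arousal = labels,
    valence_cont = ifelse(labels == "high", 0.5, -0.5),
    arousal_cont = ifelse(labels == "high", 0.5, -0.5)
  ) |> dplyr::bind_cols(feats)
}

# Linearly-coupled pair: A - B recovers the label almost exactly, but each
# of A, B alone is swamped by the shared nuisance; C is weakly informative
# alone.
make_coupled_pair_frame <- function(n = 80, seed = 42) {
  set.seed(seed)
  y <- rep(c(0, 1), n / 2)
  u <- rnorm(n, 0, 4)
  feats <- tibble::tibble(A = u + 1.5 * y + rnorm(n, 0, 0.3),
                          B = u + rnorm(n, 0, 0.3),
                          C = y + rnorm(n, 0, 1.5))
  make_feature_frame(feats, ifelse(y == 1, "high", "low"))
}

make_dominant_frame <- function(n = 60, p_noise = 2, seed = 11) {
  set.seed(seed)
  y <- rep(c(0, 1), n / 2)
  feats <- tibble::tibble(sep = y * 4 + rnorm(n, 0, 0.3))
  for (j in seq_len(p_noise)) feats[[paste0("noise", j)]] <- rnorm(n)
  make_feature_frame(feats, ifelse(y == 1, "high", "low"))
}

# Lightweight labelled cohort with the roster structure of the real study:
# 40 participants x 4 movies; `missing_all` flagged unavailable everywhere,
# `missing_partial` missing one movie; per-participant high-label counts
# controlled to exercise the minority-count rule.
make_roster_cohort <- function(valence_sparse, arousal_sparse,
                               missing_all = c(8, 24, 28),
                               missing_partial = c(17, 18, 22),
                               n_per_movie = 20) {
  roster <- tidyr::expand_grid(participant_id = 1:40, movie_id = 1:4) |>
    dplyr::mutate(has_annotations = !(participant_id %in% missing_all |
      (participant_id %in% missing_partial & movie_id == 4)))
  wins <- list()
  for (p in setdiff(1:40, missing_all)) {
    movies <- if (p %in% missing_partial) 1:3 else 1:4
    nw <- n_per_movie * length(movies)
    nv <- if (p %in% valence_sparse) 4L else nw %/% 2L
    na_ <- if (p %in% arousal_sparse) 4L else nw %/% 2L
    v <- c(rep("high", nv), rep("low", nw - nv))
    a <- c(rep("high", na_), rep("low", nw - na_))
    wins[[length(wins) + 1]] <- tibble::tibble(
      participant_id = p,
      movie_id = rep(movies, each = n_per_movie),
      window_index = rep(seq_len(n_per_movie), length(movies)),
      valence_cont = ifelse(v == "high", 0.5, -0.5),
      arousal_cont = ifelse(a == "high", 0.5, -0.5),
      valence = v, arousal = a
    )
  }
  eeg_cohort(channel_layout(), dplyr::bind_rows(wins), roster)
}

paper_valence_sparse <- c(20, 21, 23, 26, 31, 38, 39, 40)
paper_arousal_sparse <- c(11, 12, 13, 15, 20, 21, 23, 25, 26, 27, 29, 30, 35, 37, 40)
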