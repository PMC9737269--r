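# Window key: unique id for one 20-s window across the cohort.
window_key <- function(x) {
  paste(x$participant_id, x$movie_id, x$window_index, sep = ":")
}

.windows_of <- function(x) {
  if (inherits(x, "eeg_cohort")) x$windows else x
}

.fold_tibble <- function(framework, rows) {
  out <- dplyr::bind_rows(rows)
  out$framework <- framework
  out <- dplyr::select(out, "framework", "fold_id", "test_participant",
                       "test_movie", "train", "test")
  class(out) <- c("eeg_folds", class(out))
  out
}

#' Cross-validation fold generators with leakage guarantees
#'
#' Build the train/test window partitions for the four evaluation
#' frameworks:
#' * `lopo_folds()` — leave-one-person-out: one fold per participant; the
#'   held-out participant's windows (all movies) form the test set.
#' * `lomo_inter_folds()` — leave-one-movie-out, between subjects: one fold
#'   per movie; all participants contribute to both sides, no movie shared.
#' * `lomo_within_folds()` — leave-one-movie-out within one participant:
#'   four folds for the given participant, trained on their other movies.
#' * `lopmo_folds()` — leave-one-person-and-movie-out: one fold per
#'   (participant, movie) cell; training keeps only windows from other
#'   participants AND other movies.
#'
#' Window membership is tracked by key strings
#' `participant:movie:window_index`, so folds built from a cohort apply
#' directly to the matching feature matrix rows.
#'
#' @param x An `eeg_cohort` or a windows-like tibble with `participant_id`,
#'   `movie_id`, `window_index`.
#' @param participants Retained participant ids; defaults to
#'   [apply_exclusions()] under the matching scheme when `x` is a cohort.
#' @param participant For `lomo_within_folds()`, the single participant to
#'   fold (must be retained).
#' @param target Label used by the LOMO-Within exclusion rule.
#' @return A tibble of class `eeg_folds` with list-columns `train`, `test`
#'   of window keys.
#' @export
lopo_folds <- function(x, participants = NULL) {
  w <- .windows_of(x)
  if (is.null(participants)) {
    participants <- if (inherits(x, "eeg_cohort")) {
      apply_exclusions(x, "LOPO")
    } else sort(unique(w$participant_id))
  }
  if (length(participants) < 2) rlang::abort("LOPO needs at least 2 participants")
  w <- dplyr::filter(w, .data$participant_id %in% participants)
  keys <- window_key(w)
  rows <- purrr::map(participants, function(p) {
    tibble::tibble(fold_id = paste0("P", p), test_participant = p,
                   test_movie = NA,
                   train = list(keys[w$participant_id != p]),
                   test = list(keys[w$participant_id == p]))
  })
  .fold_tibble("LOPO", rows)
}

#' @rdname lopo_folds
#' @export
lomo_inter_folds <- function(x, participants = NULL) {
  w <- .windows_of(x)
  if (is.null(participants)) {
    participants <- if (inherits(x, "eeg_cohort")) {
      apply_exclusions(x, "LOMO_INTER")
    } else sort(unique(w$participant_id))
  }
  w <- dplyr::filter(w, .data$participant_id %in% participants)
  movies <- sort(unique(w$movie_id))
  if (length(movies) < 2) rlang::abort("LOMO needs at least 2 movies")
  keys <- window_key(w)
  rows <- purrr::map(movies, function(m) {
    tibble::tibble(fold_id = paste0("M", m), test_participant = NA,
                   test_movie = m,
                   train = list(keys[w$movie_id != m]),
                   test = list(keys[w$movie_id == m]))
  })
  .fold_tibble("LOMO_INTER", rows)
}

#' @rdname lopo_folds
#' @export
lomo_within_folds <- function(x, participant, participants = NULL,
                              target = "valence") {
  w <- .windows_of(x)
  if (is.null(participants)) {
    participants <- if (inherits(x, "eeg_cohort")) {
      apply_exclusions(x, "LOMO_WITHIN", target)
    } else sort(unique(w$participant_id))
  }
  if (!participant %in% participants) {
    rlang::abort("participant is excluded under the LOMO-Within rules")
  }
  w <- dplyr::filter(w, .data$participant_id == .env$participant)
  movies <- sort(unique(w$movie_id))
  if (length(movies) < 2) rlang::abort("LOMO-Within needs at least 2 movies")
  keys <- window_key(w)
  rows <- purrr::map(movies, function(m) {
    tibble::tibble(fold_id = paste0("P", participant, "M", m),
                   test_participant = participant, test_movie = m,
                   train = list(keys[w$movie_id != m]),
                   test = list(keys[w$movie_id == m]))
  })
  .fold_tibble("LOMO_WITHIN", rows)
}

#' @rdname lopo_folds
#' @export
lopmo_folds <- function(x, participants = NULL) {
  w <- .windows_of(x)
  if (is.null(participants)) {
    participants <- if (inherits(x, "eeg_cohort")) {
      apply_exclusions(x, "LOPMO")
    } else sort(unique(w$participant_id))
  }
  w <- dplyr::filter(w, .data$participant_id %in% participants)
  cells <- dplyr::distinct(w, .data$participant_id, .data$movie_id) |>
    dplyr::arrange(.data$participant_id, .data$movie_id)
  if (dplyr::n_distinct(cells$participant_id) < 2 ||
      dplyr::n_distinct(cells$movie_id) < 2) {
    rlang::abort("LOPMO needs at least 2 participants and 2 movies")
  }
  keys <- window_key(w)
  rows <- purrr::map2(cells$participant_id, cells$movie_id, function(p, m) {
    tibble::tibble(fold_id = paste0("P", p, "M", m),
                   test_participant = p, test_movie = m,
                   train = list(keys[w$participant_id != p & w$movie_id != m]),
                   test = list(keys[w$participant_id == p & w$movie_id == m]))
  })
  .fold_tibble("LOPMO", rows)
}

# Split "p:m:w" keys back into participant / movie id vectors.
.key_parts <- function(keys) {
  parts <- strsplit(keys, ":", fixed = TRUE)
  list(participant = vapply(parts, `[[`, "", 1),
       movie = vapply(parts, `[[`, "", 2))
}

#' Assert the leakage guarantees of a fold set
#'
#' Checks, for every fold, that train and test are disjoint and that the
#' framework-specific exclusion holds: LOPO — no shared participant; LOMO
#' (Inter) — no shared movie; LOMO-Within — a single participant everywhere
#' and no shared movie; LOPMO — neither shared participant nor shared movie.
#' Aborts on the first violation.
#'
#' @param folds An `eeg_folds` tibble.
#' @return `folds`, invisibly, if all assertions hold.
#' @export
check_folds <- function(folds) {
  for (i in seq_len(nrow(folds))) {
    tr <- folds$train[[i]]; te <- folds$test[[i]]
    if (length(intersect(tr, te)) > 0) {
      rlang::abort(paste0("fold ", folds$fold_id[i], ": train/test overlap"))
    }
    ptr <- .key_parts(tr); pte <- .key_parts(te)
    fw <- folds$framework[i]
    bad <- switch(fw,
      LOPO = length(intersect(ptr$participant, pte$participant)) > 0,
      LOMO_INTER = length(intersect(ptr$movie, pte$movie)) > 0,
      LOMO_WITHIN = length(unique(c(ptr$participant, pte$participant))) != 1 ||
        length(intersect(ptr$movie, pte$movie)) > 0,
      LOPMO = length(intersect(ptr$participant, pte$participant)) > 0 ||
        length(intersect(ptr$movie, pte$movie)) > 0,
      rlang::abort(paste0("unknown framework: ", fw))
    )
    if (bad) {
      rlang::abort(paste0("fold ", folds$fold_id[i], ": leakage under ", fw))
    }
  }
  invisible(folds)
}
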