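#' Combine annotator ratings and binarize affect labels
#'
#' Collapses the external annotators' continuous valence/arousal ratings to
#' one value per 20-s period and applies the zero affect threshold: strictly
#' positive combined values map to "high", everything else (including exact
#' zero) to "low". Missing single-annotator entries are dropped from the
#' combination for that period.
#'
#' @param annotations Tibble with columns `participant_id`, `movie_id`,
#'   `period_index`, `annotator_id`, `valence`, `arousal` (one row per
#'   annotator per period).
#' @param combine `"mean"` (arithmetic mean of available annotators, the
#'   default) or `"majority"` (majority vote on per-annotator binarized
#'   labels; ties resolve to "low"; the reported continuous value is still
#'   the mean).
#' @return Tibble with one row per (participant, movie, period):
#'   `valence_cont`, `arousal_cont`, `valence`, `arousal` ("low"/"high").
#' @examples
#' ann <- tibble::tibble(participant_id = 1, movie_id = 1, period_index = 1,
#'                       annotator_id = 1:3, valence = c(0.6, -0.3, 0),
#'                       arousal = c(-0.2, -0.4, -0.1))
#' binarize_labels(ann)
#' @export
binarize_labels <- function(annotations, combine = c("mean", "majority")) {
  combine <- match.arg(combine)
  if (nrow(annotations) == 0) rlang::abort("empty annotation series")
  lab <- function(x) ifelse(x > 0, "high", "low")
  out <- annotations |>
    dplyr::group_by(.data$participant_id, .data$movie_id, .data$period_index) |>
    dplyr::summarise(
      valence_cont = mean(.data$valence, na.rm = TRUE),
      arousal_cont = mean(.data$arousal, na.rm = TRUE),
      valence_high_votes = sum(.data$valence > 0, na.rm = TRUE),
      arousal_high_votes = sum(.data$arousal > 0, na.rm = TRUE),
      n_annotators = sum(!is.na(.data$valence)),
      .groups = "drop"
    )
  if (combine == "mean") {
    out <- dplyr::mutate(out, valence = lab(.data$valence_cont),
                         arousal = lab(.data$arousal_cont))
  } else {
    out <- dplyr::mutate(
      out,
      valence = ifelse(.data$valence_high_votes > .data$n_annotators / 2,
                       "high", "low"),
      arousal = ifelse(.data$arousal_high_votes > .data$n_annotators / 2,
                       "high", "low")
    )
  }
  dplyr::select(out, "participant_id", "movie_id", "period_index",
                "valence_cont", "arousal_cont", "valence", "arousal") |>
    dplyr::arrange(.data$participant_id, .data$movie_id, .data$period_index)
}

#' Cut a movie's EEG into label-aligned 20-s windows
#'
#' Annotation period `k` (1-based) covers samples
#' `[(k-1) * 20 * fs + 1, k * 20 * fs]`. The first and last annotated periods
#' are discarded (both the label and the EEG), so a movie with `P` periods
#' yields `P - 2` contiguous, non-overlapping windows.
#'
#' @param eeg Channels x samples numeric matrix for one (participant, movie).
#' @param annotations Annotation rows for that participant and movie (long
#'   format, as in [binarize_labels()]).
#' @param layout An `eeg_layout`.
#' @param combine Annotator combination rule, passed to [binarize_labels()].
#' @return Windows tibble: `participant_id`, `movie_id`, `window_index` (the
#'   source period index), `valence_cont`, `arousal_cont`, `valence`,
#'   `arousal`, and an `eeg` list-column of 14 x 2560 matrices.
#' @export
segment_movie <- function(eeg, annotations, layout = channel_layout(),
                          combine = "mean") {
  labels <- binarize_labels(annotations, combine)
  if (dplyr::n_distinct(labels$participant_id) != 1 ||
      dplyr::n_distinct(labels$movie_id) != 1) {
    rlang::abort("segment_movie expects annotations for a single (participant, movie)")
  }
  n_periods <- nrow(labels)
  if (n_periods < 3) rlang::abort("need at least 3 annotation periods")
  wlen <- as.integer(20 * layout$sampling_rate)
  if (nrow(eeg) != length(layout$names)) {
    rlang::abort("EEG row count does not match layout channel count")
  }
  if (!all(is.finite(eeg))) rlang::abort("non-finite samples in EEG")
  if (abs(ncol(eeg) - n_periods * wlen) > wlen) {
    rlang::abort("EEG duration and annotation length disagree by more than one period")
  }
  if (ncol(eeg) < (n_periods - 1) * wlen) {
    rlang::abort("EEG too short to cover the annotated periods")
  }
  labels <- labels[order(labels$period_index), ]
  keep <- labels[-c(1, n_periods), ]
  wins <- purrr::map(keep$period_index, function(k) {
    s0 <- (k - 1L) * wlen
    unname(eeg[, (s0 + 1L):(s0 + wlen), drop = FALSE])
  })
  tibble::tibble(
    participant_id = keep$participant_id,
    movie_id = keep$movie_id,
    window_index = keep$period_index,
    valence_cont = keep$valence_cont,
    arousal_cont = keep$arousal_cont,
    valence = keep$valence,
    arousal = keep$arousal,
    eeg = wins
  )
}

#' Assemble a cohort dataset
#'
#' Bundles the layout, the window collection and a per-(participant, movie)
#' annotation-availability roster into an `eeg_cohort`.
#'
#' @param layout An `eeg_layout`.
#' @param windows Windows tibble (as from [segment_movie()], row-bound over
#'   the cohort). May omit the `eeg` column for label-only analyses.
#' @param roster Tibble `participant_id`, `movie_id`, `has_annotations`. If
#'   NULL, derived from `windows` with every present cell marked available.
#' @return An object of class `eeg_cohort`.
#' @export
eeg_cohort <- function(layout, windows, roster = NULL) {
  if (is.null(roster)) {
    roster <- dplyr::distinct(windows, .data$participant_id, .data$movie_id) |>
      dplyr::mutate(has_annotations = TRUE)
  }
  present <- dplyr::semi_join(
    windows, dplyr::filter(roster, .data$has_annotations),
    by = c("participant_id", "movie_id")
  )
  if (nrow(present) != nrow(windows)) {
    rlang::abort("windows present for (participant, movie) cells not in the roster")
  }
  dup <- windows |>
    dplyr::count(.data$participant_id, .data$movie_id, .data$window_index) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) rlang::abort("duplicate window indices within a (participant, movie)")
  structure(list(layout = layout, windows = windows, roster = roster),
            class = "eeg_cohort")
}

#' @export
print.eeg_cohort <- function(x, ...) {
  cat("<eeg_cohort> ", dplyr::n_distinct(x$windows$participant_id),
      " participants, ", dplyr::n_distinct(x$windows$movie_id), " movies, ",
      nrow(x$windows), " windows\n", sep = "")
  invisible(x)
}

#' Participant exclusion rules per cross-validation framework
#'
#' Drops participants according to the framework in use: participants with no
#' annotated movies are always removed; frameworks that build per-participant
#' or fully unseen-cell models (LOMO-Within, LOPMO) additionally remove
#' participants with partially missing movies; LOMO-Within further removes
#' participants whose minority-class window count for the target label falls
#' below `min_minority` (default 10), mirroring the extreme-imbalance rule.
#'
#' @param cohort An `eeg_cohort` with labelled windows.
#' @param scheme One of "LOPO", "LOMO_INTER", "LOMO_WITHIN", "LOPMO".
#' @param target "valence" or "arousal" (used by the LOMO-Within imbalance
#'   rule).
#' @param min_minority Minimum minority-class window count for LOMO-Within.
#' @return Sorted vector of retained participant ids.
#' @export
apply_exclusions <- function(cohort, scheme = c("LOPO", "LOMO_INTER",
                                                "LOMO_WITHIN", "LOPMO"),
                             target = c("valence", "arousal"),
                             min_minority = 10) {
  scheme <- match.arg(scheme)
  target <- match.arg(target)
  avail <- cohort$roster |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(n_movies = dplyr::n(),
                     n_annotated = sum(.data$has_annotations),
                     .groups = "drop")
  retained <- dplyr::filter(avail, .data$n_annotated > 0)
  if (scheme %in% c("LOMO_WITHIN", "LOPMO")) {
    retained <- dplyr::filter(retained, .data$n_annotated == .data$n_movies)
  }
  ids <- retained$participant_id
  if (scheme == "LOMO_WITHIN") {
    counts <- cohort$windows |>
      dplyr::filter(.data$participant_id %in% ids) |>
      dplyr::count(.data$participant_id, label = .data[[target]]) |>
      tidyr::pivot_wider(names_from = "label", values_from = "n",
                         values_fill = 0)
    for (cl in c("low", "high")) if (!cl %in% names(counts)) counts[[cl]] <- 0
    keep <- counts$participant_id[pmin(counts$low, counts$high) >= min_minority]
    ids <- intersect(ids, keep)
  }
  ids <- sort(ids)
  if (length(ids) == 0) rlang::abort("no participants retained after exclusions")
  ids
}

#' Write / read a cohort as plain-text files
#'
#' The on-disk container is a directory holding `layout.json`, `roster.csv`,
#' `windows.csv` (window metadata and labels) and `eeg.csv` (one row per
#' window x channel, sample columns). Doubles are written with readr's
#' shortest-round-trip formatting, so a write/read cycle reproduces the
#' cohort bit-for-bit.
#'
#' @param cohort An `eeg_cohort`.
#' @param dir Directory path (created if needed).
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` returns the
#'   reconstructed `eeg_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  # doubles are serialised as %.17g so strtod-based parsing restores them
  # bit-for-bit
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(names = cohort$layout$names,
         pairs = cohort$layout$pairs,
         sampling_rate = cohort$layout$sampling_rate),
    file.path(dir, "layout.json"), auto_unbox = TRUE, digits = NA
  )
  .write_exact_csv(cohort$roster, file.path(dir, "roster.csv"))
  meta <- dplyr::select(cohort$windows, -dplyr::any_of("eeg"))
  .write_exact_csv(meta, file.path(dir, "windows.csv"))
  if ("eeg" %in% names(cohort$windows)) {
    flat <- purrr::pmap_dfr(
      cohort$windows[, c("participant_id", "movie_id", "window_index", "eeg")],
      function(participant_id, movie_id, window_index, eeg) {
        m <- matrix(sprintf("%.17g", eeg), nrow(eeg), ncol(eeg))
        colnames(m) <- sprintf("s%04d", seq_len(ncol(m)))
        dplyr::bind_cols(
          tibble::tibble(participant_id = participant_id, movie_id = movie_id,
                         window_index = window_index,
                         channel = cohort$layout$names),
          tibble::as_tibble(m)
        )
      }
    )
    readr::write_csv(flat, file.path(dir, "eeg.csv"), progress = FALSE,
                     quote = "none")
  }
  invisible(dir)
}

.write_exact_csv <- function(df, path) {
  df <- dplyr::mutate(df, dplyr::across(
    dplyr::where(is.double), ~ sprintf("%.17g", .x)))
  readr::write_csv(df, path, progress = FALSE, quote = "none")
}

.read_exact_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE,
                                    stringsAsFactors = FALSE))
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  lj <- jsonlite::read_json(file.path(dir, "layout.json"), simplifyVector = TRUE)
  layout <- channel_layout(sampling_rate = lj$sampling_rate)
  stopifnot(identical(layout$names, lj$names))
  roster <- .read_exact_csv(file.path(dir, "roster.csv"))
  meta <- .read_exact_csv(file.path(dir, "windows.csv"))
  eeg_path <- file.path(dir, "eeg.csv")
  if (file.exists(eeg_path)) {
    flat <- .read_exact_csv(eeg_path)
    key <- paste(flat$participant_id, flat$movie_id, flat$window_index)
    smat <- as.matrix(flat[, grepl("^s\\d+$", names(flat))])
    mats <- lapply(split(seq_len(nrow(flat)), factor(key, levels = unique(key))),
                   function(i) unname(smat[i, , drop = FALSE]))
    meta$eeg <- mats[paste(meta$participant_id, meta$movie_id, meta$window_index)]
    names(meta$eeg) <- NULL
  }
  eeg_cohort(layout, meta, roster)
}

#' Read / write the annotation CSV format
#'
#' Long-format external-annotator table: one row per (participant, movie,
#' period, annotator) with continuous `valence` and `arousal` ratings.
#'
#' @param path CSV file path.
#' @param annotations Annotation tibble.
#' @return A tibble (`read_annotations`) or `path` invisibly.
#' @export
read_annotations <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_integer(),
    movie_id = readr::col_integer(),
    period_index = readr::col_integer(),
    annotator_id = readr::col_integer(),
    valence = readr::col_double(),
    arousal = readr::col_double()
  ), progress = FALSE)
}

#' @rdname read_annotations
#' @export
write_annotations <- function(annotations, path) {
  readr::write_csv(annotations, path, progress = FALSE)
  invisible(path)
}
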