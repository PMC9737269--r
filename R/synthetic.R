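#' Synthetic cohort generator configuration
#'
#' Describes a synthetic affect-annotated EEG cohort: per-movie latent binary
#' affect states follow a two-state Markov chain; channel signals are
#' 1/f^beta coloured noise plus band-limited oscillations whose log-power
#' (and optionally spectral slope) is shifted by the latent state on
#' designated channels; participant- and movie-level random effects perturb
#' channel amplitudes; three annotators report the state as a continuous
#' value (+0.5 / -0.5) with Gaussian noise and independent sign flips.
#'
#' @param n_participants Number of participants.
#' @param movie_durations Numeric vector of movie durations in seconds (one
#'   movie per entry; 20-s annotation periods).
#' @param stationary_valence,stationary_arousal Per-movie stationary
#'   probability of the "high" state.
#' @param persistence Markov-chain persistence (probability of copying the
#'   previous state before redrawing from the stationary law).
#' @param effects Tibble `target`, `channel`, `band`, `shift`: log band-power
#'   shift applied in the high state of `target` on `channel`.
#' @param slope_effects Tibble `target`, `channel`, `shift`: added to the
#'   noise spectral slope beta in the high state.
#' @param participant_sd,movie_sd SD of per-channel log-amplitude random
#'   effects for participants and movies.
#' @param label_logit_sd SD of the per-participant logit shift applied to the
#'   stationary probabilities (inter-subject imbalance variability).
#' @param n_annotators Number of external annotators (default 3).
#' @param flip_prob Per-annotator, per-period probability of flipping the
#'   sign of the reported value.
#' @param annotator_sd SD of Gaussian annotator noise.
#' @param noise_beta Baseline spectral slope of the coloured noise.
#' @param noise_floor SD of the additive white noise floor.
#' @param osc_amp Baseline amplitude of effect oscillations in the low state.
#' @param missing_all Participant ids missing annotations for all movies.
#' @param missing_partial Tibble `participant_id`, `movie_id` of cells with
#'   missing annotations.
#' @param seed RNG seed.
#' @param layout An `eeg_layout`.
#' @param bands Band definition tibble.
#' @return A validated list of class `eeg_generator_config`.
#' @export
generator_config <- function(n_participants = 8,
                             movie_durations = rep(800, 4),
                             stationary_valence = c(0.45, 0.79, 0.03, 0.45),
                             stationary_arousal = c(0.40, 0.57, 0.02, 0.40),
                             persistence = 0.8,
                             effects = tibble::tibble(
                               target = c("valence", "valence", "arousal", "arousal"),
                               channel = c("T7", "T8", "AF3", "AF4"),
                               band = c("gamma", "gamma", "theta", "theta"),
                               shift = c(1, 1, 0.8, 0.8)
                             ),
                             slope_effects = tibble::tibble(
                               target = c("valence", "valence"),
                               channel = c("T7", "T8"),
                               shift = c(0.3, 0.3)
                             ),
                             participant_sd = 0.2, movie_sd = 0.1,
                             label_logit_sd = 0.3,
                             n_annotators = 3, flip_prob = 0.1,
                             annotator_sd = 0.1,
                             noise_beta = 1, noise_floor = 0.1, osc_amp = 1,
                             missing_all = integer(0),
                             missing_partial = tibble::tibble(
                               participant_id = integer(), movie_id = integer()
                             ),
                             seed = 1,
                             layout = channel_layout(),
                             bands = band_definitions()) {
  n_movies <- length(movie_durations)
  stopifnot(
    n_participants >= 1, n_movies >= 1,
    all(movie_durations >= 60),
    length(stationary_valence) == n_movies,
    length(stationary_arousal) == n_movies,
    all(stationary_valence >= 0 & stationary_valence <= 1),
    all(stationary_arousal >= 0 & stationary_arousal <= 1),
    persistence >= 0 && persistence <= 1,
    flip_prob >= 0 && flip_prob <= 1,
    n_annotators >= 1
  )
  if (nrow(effects) > 0) {
    stopifnot(all(effects$channel %in% layout$names),
              all(effects$band %in% bands$band),
              all(effects$target %in% c("valence", "arousal")))
  }
  if (nrow(slope_effects) > 0) {
    stopifnot(all(slope_effects$channel %in% layout$names),
              all(slope_effects$target %in% c("valence", "arousal")))
  }
  structure(as.list(environment())[c(
    "n_participants", "movie_durations", "stationary_valence",
    "stationary_arousal", "persistence", "effects", "slope_effects",
    "participant_sd", "movie_sd", "label_logit_sd", "n_annotators",
    "flip_prob", "annotator_sd", "noise_beta", "noise_floor", "osc_amp",
    "missing_all", "missing_partial", "seed", "layout", "bands"
  )], class = "eeg_generator_config")
}

#' Named generator presets
#'
#' * `"mini"` — the default fast-CI cohort: 8 participants x 4 movies x 40
#'   periods, imbalanced per-movie class probabilities emulating the real
#'   stimuli (one movie ~79%/57% high valence/arousal, one ~3%/2%), modest
#'   planted effects.
#' * `"tiny"` — 3 participants x 2 movies x 8 periods, for unit tests.
#' * `"chance"` — 6 x 4 x 14 periods, zero effect sizes, zero annotator
#'   flips, balanced classes: the chance-level calibration condition.
#' * `"planted"` — same shape with a strong T7/T8 gamma log-power (+ slope)
#'   valence effect and clean labels.
#'
#' @param name Preset name.
#' @param seed RNG seed to embed in the config.
#' @return An `eeg_generator_config`.
#' @export
cohort_preset <- function(name = c("mini", "tiny", "chance", "planted"),
                          seed = 1) {
  name <- match.arg(name)
  no_eff <- tibble::tibble(target = character(), channel = character(),
                           band = character(), shift = numeric())
  no_slope <- tibble::tibble(target = character(), channel = character(),
                             shift = numeric())
  switch(name,
    mini = generator_config(seed = seed),
    tiny = generator_config(
      n_participants = 3, movie_durations = rep(160, 2),
      stationary_valence = c(0.5, 0.5), stationary_arousal = c(0.5, 0.5),
      persistence = 0.4,
      effects = tibble::tibble(target = "valence", channel = c("T7", "T8"),
                               band = "gamma", shift = 1),
      slope_effects = no_slope, flip_prob = 0, label_logit_sd = 0, seed = seed
    ),
    chance = generator_config(
      n_participants = 6, movie_durations = rep(440, 4),
      stationary_valence = rep(0.5, 4), stationary_arousal = rep(0.5, 4),
      persistence = 0.4,
      effects = no_eff, slope_effects = no_slope,
      participant_sd = 0, movie_sd = 0,
      flip_prob = 0, label_logit_sd = 0, seed = seed
    ),
    planted = generator_config(
      n_participants = 6, movie_durations = rep(280, 4),
      stationary_valence = rep(0.5, 4), stationary_arousal = rep(0.5, 4),
      effects = tibble::tibble(target = "valence", channel = c("T7", "T8"),
                               band = "gamma", shift = 1.5),
      slope_effects = tibble::tibble(target = "valence",
                                     channel = c("T7", "T8"), shift = 0.4),
      flip_prob = 0, label_logit_sd = 0, seed = seed
    )
  )
}

# 1/f^beta coloured noise, unit variance, via spectral synthesis.
.colored_noise <- function(n, beta) {
  half <- n %/% 2
  mag <- seq_len(half)^(-beta / 2)
  ph <- stats::runif(half) * 2 * pi
  pos <- complex(modulus = mag, argument = ph)
  spec <- complex(real = numeric(n))
  spec[2:(half + 1)] <- pos
  spec[half + 1] <- complex(real = mag[half] * cos(ph[half]))  # real Nyquist
  spec[n:(n - half + 2)] <- Conj(pos[seq_len(half - 1)])
  x <- Re(stats::fft(spec, inverse = TRUE)) / sqrt(n)
  s <- stats::sd(x)
  if (s == 0) return(x)
  (x - mean(x)) / s
}

#' Generate a synthetic affect-annotated EEG cohort
#'
#' Draws latent valence and arousal state chains per (participant, movie),
#' synthesises the channel signals period by period, writes the annotator
#' series, and assembles the result through the same segmentation and
#' binarization path used for real data (first and last periods dropped).
#'
#' @param cfg An `eeg_generator_config`.
#' @param signals Generate the EEG signals (default). With `signals = FALSE`
#'   only states, annotations and labelled windows are produced (no `eeg`
#'   column) — enough for fold construction, exclusion logic and label
#'   statistics at full cohort scale.
#' @return An `eeg_cohort` with attributes `truth` (per-period latent state
#'   table), `annotations` (the long annotator table) and `config`.
#' @examples
#' cohort <- generate_cohort(cohort_preset("tiny"))
#' cohort
#' @export
generate_cohort <- function(cfg, signals = TRUE) {
  stopifnot(inherits(cfg, "eeg_generator_config"))
  set.seed(cfg$seed)
  layout <- cfg$layout
  nch <- length(layout$names)
  n_movies <- length(cfg$movie_durations)
  wlen <- as.integer(20 * layout$sampling_rate)
  periods <- pmax(3L, as.integer(floor(cfg$movie_durations / 20)))

  # random effects drawn up front so structure is stable under loop changes
  amp_p <- matrix(stats::rnorm(cfg$n_participants * nch, 0, cfg$participant_sd),
                  cfg$n_participants, nch)
  amp_m <- matrix(stats::rnorm(n_movies * nch, 0, cfg$movie_sd), n_movies, nch)
  logit_p <- matrix(stats::rnorm(cfg$n_participants * 2, 0, cfg$label_logit_sd),
                    cfg$n_participants, 2)

  clamp <- function(p) pmin(pmax(p, 1e-3), 1 - 1e-3)
  draw_chain <- function(p_high, n) {
    s <- integer(n)
    s[1] <- stats::rbinom(1, 1, p_high)
    for (t in seq_len(n)[-1]) {
      s[t] <- if (stats::runif(1) < cfg$persistence) s[t - 1] else
        stats::rbinom(1, 1, p_high)
    }
    s
  }

  eff_by_ch <- if (nrow(cfg$effects) > 0) {
    dplyr::left_join(cfg$effects, cfg$bands, by = "band") |>
      dplyr::mutate(width = .data$f_high - .data$f_low)
  } else cfg$effects

  missing_cell <- function(p, m) {
    p %in% cfg$missing_all ||
      any(cfg$missing_partial$participant_id == p &
            cfg$missing_partial$movie_id == m)
  }

  windows_list <- list(); truth_list <- list(); ann_list <- list()
  roster <- tidyr::expand_grid(participant_id = seq_len(cfg$n_participants),
                               movie_id = seq_len(n_movies)) |>
    dplyr::mutate(has_annotations = !purrr::map2_lgl(
      .data$participant_id, .data$movie_id, missing_cell))

  for (p in seq_len(cfg$n_participants)) {
    for (m in seq_len(n_movies)) {
      np <- periods[m]
      pv <- clamp(stats::plogis(stats::qlogis(clamp(cfg$stationary_valence[m])) +
                                  logit_p[p, 1]))
      pa <- clamp(stats::plogis(stats::qlogis(clamp(cfg$stationary_arousal[m])) +
                                  logit_p[p, 2]))
      sv <- draw_chain(pv, np)
      sa <- draw_chain(pa, np)
      truth_list[[length(truth_list) + 1]] <- tibble::tibble(
        participant_id = p, movie_id = m, period_index = seq_len(np),
        valence_state = sv, arousal_state = sa
      )
      gain <- exp(amp_p[p, ] + amp_m[m, ])
      eeg <- if (signals) matrix(0, nch, np * wlen) else NULL
      for (t in if (signals) seq_len(np) else integer(0)) {
        state <- c(valence = sv[t], arousal = sa[t])
        seg <- matrix(0, nch, wlen)
        for (ch in seq_len(nch)) {
          chname <- layout$names[ch]
          beta <- cfg$noise_beta
          if (nrow(cfg$slope_effects) > 0) {
            sel <- cfg$slope_effects$channel == chname
            if (any(sel)) {
              beta <- beta + sum(cfg$slope_effects$shift[sel] *
                                   state[cfg$slope_effects$target[sel]])
            }
          }
          x <- .colored_noise(wlen, beta)
          if (nrow(eff_by_ch) > 0) {
            sel <- which(eff_by_ch$channel == chname)
            for (e in sel) {
              a <- cfg$osc_amp *
                exp(eff_by_ch$shift[e] / 2 * state[[eff_by_ch$target[e]]])
              f0 <- stats::runif(1, eff_by_ch$f_low[e] + 1,
                                 eff_by_ch$f_high[e] - 1)
              ph <- stats::runif(1, 0, 2 * pi)
              tt <- seq_len(wlen) / layout$sampling_rate
              x <- x + a * sqrt(2) * sin(2 * pi * f0 * tt + ph)
            }
          }
          seg[ch, ] <- gain[ch] * x +
            stats::rnorm(wlen, 0, cfg$noise_floor)
        }
        eeg[, ((t - 1) * wlen + 1):(t * wlen)] <- seg
      }
      if (roster$has_annotations[roster$participant_id == p &
                                   roster$movie_id == m]) {
        for (a in seq_len(cfg$n_annotators)) {
          v <- ifelse(sv == 1, 0.5, -0.5) + stats::rnorm(np, 0, cfg$annotator_sd)
          u <- ifelse(sa == 1, 0.5, -0.5) + stats::rnorm(np, 0, cfg$annotator_sd)
          fv <- stats::runif(np) < cfg$flip_prob
          fa <- stats::runif(np) < cfg$flip_prob
          ann_list[[length(ann_list) + 1]] <- tibble::tibble(
            participant_id = p, movie_id = m, period_index = seq_len(np),
            annotator_id = a,
            valence = ifelse(fv, -v, v), arousal = ifelse(fa, -u, u)
          )
        }
        ann_pm <- dplyr::bind_rows(utils::tail(ann_list, cfg$n_annotators))
        windows_list[[length(windows_list) + 1]] <- if (signals) {
          segment_movie(eeg, ann_pm, layout)
        } else {
          lb <- binarize_labels(ann_pm)
          lb <- lb[order(lb$period_index), ][-c(1, np), ]
          tibble::tibble(
            participant_id = lb$participant_id, movie_id = lb$movie_id,
            window_index = lb$period_index,
            valence_cont = lb$valence_cont, arousal_cont = lb$arousal_cont,
            valence = lb$valence, arousal = lb$arousal
          )
        }
      }
    }
  }
  windows <- dplyr::bind_rows(windows_list)
  cohort <- eeg_cohort(layout, windows, roster)
  attr(cohort, "truth") <- dplyr::bind_rows(truth_list)
  attr(cohort, "annotations") <- dplyr::bind_rows(ann_list)
  attr(cohort, "config") <- cfg
  cohort
}

#' Pairwise annotator agreement after binarization
#'
#' Mean over annotator pairs and periods of the indicator that the two
#' annotators assign the same binarized ("high" iff value > 0) label.
#'
#' @param annotations Long annotation tibble (see [read_annotations()]).
#' @param target "valence" or "arousal".
#' @return Scalar agreement fraction in [0, 1].
#' @export
annotator_agreement <- function(annotations, target = c("valence", "arousal")) {
  target <- match.arg(target)
  wide <- annotations |>
    dplyr::mutate(lab = .data[[target]] > 0) |>
    dplyr::select("participant_id", "movie_id", "period_index",
                  "annotator_id", "lab") |>
    tidyr::pivot_wider(names_from = "annotator_id", values_from = "lab")
  cols <- setdiff(names(wide), c("participant_id", "movie_id", "period_index"))
  if (length(cols) < 2) rlang::abort("need at least two annotators")
  pairs <- utils::combn(cols, 2, simplify = FALSE)
  mean(purrr::map_dbl(pairs, function(pr) {
    mean(wide[[pr[1]]] == wide[[pr[2]]], na.rm = TRUE)
  }))
}
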