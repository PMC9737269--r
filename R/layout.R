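#' Standard 14-channel EEG layout
#'
#' The consumer-headset montage used throughout the package: 14 electrodes on
#' international 10-20 positions, sampled at 128 Hz, with the seven symmetric
#' left/right pairs used for hemispheric asymmetry features. Pair lobe labels
#' follow the convention AF, F (F7/F8), F34 (F3/F4), FC, T, P, O.
#'
#' @param sampling_rate Sampling rate in Hz (default 128).
#' @return An object of class `eeg_layout`: a list with `names` (ordered
#'   channel labels), `pairs` (tibble with `lobe`, `left`, `right`) and
#'   `sampling_rate`.
#' @examples
#' layout <- channel_layout()
#' layout$pairs
#' @export
channel_layout <- function(sampling_rate = 128) {
  names <- c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1",
             "O2", "P8", "T8", "FC6", "F4", "F8", "AF4")
  pairs <- tibble::tibble(
    lobe  = c("AF",  "F",  "F34", "FC",  "T",  "P",  "O"),
    left  = c("AF3", "F7", "F3",  "FC5", "T7", "P7", "O1"),
    right = c("AF4", "F8", "F4",  "FC6", "T8", "P8", "O2")
  )
  stopifnot(
    length(names) == 14L, !anyDuplicated(names),
    all(pairs$left %in% names), all(pairs$right %in% names),
    all(pairs$left != pairs$right),
    is.numeric(sampling_rate), sampling_rate > 0
  )
  structure(
    list(names = names, pairs = pairs, sampling_rate = sampling_rate),
    class = "eeg_layout"
  )
}

#' EEG frequency band definitions
#'
#' The five bands used for band log-power and asymmetry features. Slow alpha
#' is fixed at (8, 10) Hz; the remaining edges follow the DEAP/AMIGOS-lineage
#' convention and can be overridden.
#'
#' @param theta,slow_alpha,alpha,beta,gamma Length-2 numeric `(f_low, f_high)`
#'   in Hz.
#' @return A tibble with columns `band`, `f_low`, `f_high`.
#' @examples
#' band_definitions()
#' @export
band_definitions <- function(theta = c(4, 8), slow_alpha = c(8, 10),
                             alpha = c(8, 13), beta = c(13, 30),
                             gamma = c(30, 45)) {
  bands <- tibble::tibble(
    band   = c("theta", "slow_alpha", "alpha", "beta", "gamma"),
    f_low  = c(theta[1], slow_alpha[1], alpha[1], beta[1], gamma[1]),
    f_high = c(theta[2], slow_alpha[2], alpha[2], beta[2], gamma[2])
  )
  if (any(bands$f_low <= 0) || any(bands$f_low >= bands$f_high) ||
      any(bands$f_high > 64)) {
    rlang::abort("band edges must satisfy 0 < f_low < f_high <= 64 (Nyquist at 128 Hz)")
  }
  bands
}

# Families computed once per channel (no band), in fixed registry order.
.nonlinear_families <- c("HM", "HC", "DFA", "PFD", "HFD",
                         "SpecEnt", "svdEnt", "FI")

#' Feature descriptor registry
#'
#' Enumerates the full 217-feature set in its fixed extraction order:
#' 14 channels x 5 bands of band log-power (70, "PSD"), 7 symmetric pairs x
#' 5 bands of hemispheric asymmetry (35, "Asymm"), then 14 channels x 8
#' per-channel descriptors (112): Hjorth mobility/complexity, DFA exponent,
#' Petrosian and Higuchi fractal dimensions, spectral entropy, SVD entropy
#' and Fisher information. Names follow the "[Electrode, Feature, Band]"
#' convention, with the lobe label in place of the electrode for asymmetries
#' and an empty band except for PSD/Asymm.
#'
#' @param layout An `eeg_layout`.
#' @param bands A band definition tibble from [band_definitions()].
#' @return A tibble with columns `name`, `family`, `channel`, `band`,
#'   `original_amigos`, with exactly 217 rows.
#' @examples
#' reg <- feature_registry()
#' dplyr::count(reg, family)
#' @export
feature_registry <- function(layout = channel_layout(),
                             bands = band_definitions()) {
  psd <- tidyr::expand_grid(channel = layout$names, band = bands$band) |>
    dplyr::mutate(family = "PSD",
                  name = paste(.data$channel, "PSD", .data$band),
                  original_amigos = TRUE)
  asym <- tidyr::expand_grid(channel = layout$pairs$lobe, band = bands$band) |>
    dplyr::mutate(family = "Asymm",
                  name = paste(.data$channel, "Asymm", .data$band),
                  original_amigos = TRUE)
  nl <- tidyr::expand_grid(channel = layout$names,
                           family = .nonlinear_families) |>
    dplyr::mutate(band = NA_character_,
                  name = paste(.data$channel, .data$family),
                  original_amigos = FALSE)
  reg <- dplyr::bind_rows(psd, asym, nl) |>
    dplyr::select("name", "family", "channel", "band", "original_amigos")
  stopifnot(
    nrow(reg) == 217L,
    !anyDuplicated(reg$name),
    sum(reg$family == "PSD") == 70L,
    sum(reg$family == "Asymm") == 35L,
    sum(!reg$original_amigos) == 112L,
    sum(reg$original_amigos) == 105L
  )
  reg
}
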