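#' Welch power spectral density
#'
#' Average periodogram over Hann-tapered segments of `window_len` samples
#' (1 s at 128 Hz, giving a 1 Hz frequency grid) with 50% overlap by default.
#' The one-sided density is scaled so that the integrated power (sum over the
#' 1 Hz grid) approximates the signal's mean square.
#'
#' @param x Numeric vector, one channel of one window.
#' @param fs Sampling rate in Hz.
#' @param window_len Segment length in samples.
#' @param overlap Fractional overlap between consecutive segments.
#' @return A tibble of class `eeg_spectrum` with columns `frequency` (Hz,
#'   0..Nyquist) and `power`.
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 20, by = 1 / 128))
#' spec <- welch_psd(x)
#' spec$frequency[which.max(spec$power)]
#' @export
welch_psd <- function(x, fs = 128, window_len = 128, overlap = 0.5) {
  n <- length(x)
  if (n < window_len) rlang::abort("signal shorter than one Welch segment")
  if (!all(is.finite(x))) rlang::abort("non-finite samples in signal")
  step <- max(1L, as.integer(round(window_len * (1 - overlap))))
  starts <- seq.int(1L, n - window_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(window_len) - 1) / window_len)
  # constant-detrended, Hann-tapered segments as columns; one FFT call
  seg <- vapply(starts, function(s) {
    xs <- x[s:(s + window_len - 1L)]
    (xs - mean(xs)) * w
  }, numeric(window_len))
  ft <- stats::mvfft(as.matrix(seg))
  half <- window_len %/% 2 + 1L
  pxx <- rowMeans(Mod(ft[seq_len(half), , drop = FALSE])^2) / (fs * sum(w^2))
  # one-sided: double everything except DC and Nyquist
  scale2 <- rep(2, half); scale2[1] <- 1
  if (window_len %% 2 == 0) scale2[half] <- 1
  out <- tibble::tibble(
    frequency = (seq_len(half) - 1) * fs / window_len,
    power = pxx * scale2
  )
  class(out) <- c("eeg_spectrum", class(out))
  out
}

#' Band-average log power
#'
#' Mean spectral power over the bins from `f_low` to `f_high` inclusive on
#' the spectrum's grid, normalised by the band width `f_high - f_low` and
#' log-transformed (natural log). A floor of `eps` is applied before the log
#' so that silent bands (e.g. from constant test signals) stay finite.
#'
#' @param spec An `eeg_spectrum` (or any tibble with `frequency`, `power`).
#' @param f_low,f_high Band edges in Hz.
#' @param eps Floor applied to the band average before the log.
#' @return Scalar log band power.
#' @export
band_logpower <- function(spec, f_low, f_high, eps = 1e-12) {
  if (f_low >= f_high) rlang::abort("f_low must be < f_high")
  if (f_low < min(spec$frequency) - 1e-9 || f_high > max(spec$frequency) + 1e-9) {
    rlang::abort("band outside spectrum range")
  }
  sel <- spec$frequency >= f_low - 1e-9 & spec$frequency <= f_high + 1e-9
  log(max(sum(spec$power[sel]) / (f_high - f_low), eps))
}

#' Hemispheric spectral asymmetry
#'
#' Difference of band log-powers between a left-hemisphere electrode and its
#' right-hemisphere mirror.
#'
#' @param psd_left,psd_right Band log-power values for the same band.
#' @return `psd_left - psd_right`.
#' @export
asymmetry <- function(psd_left, psd_right) psd_left - psd_right

#' Hjorth mobility and complexity
#'
#' Mobility is the square root of the variance of the first difference of the
#' signal normalised by the signal variance — an estimate of mean frequency.
#' Complexity is the mobility of the first difference divided by the mobility
#' of the signal, reflecting bandwidth.
#'
#' @param x Numeric vector, length >= 3 with nonzero variance.
#' @return Scalar.
#' @export
hjorth_mobility <- function(x) {
  if (length(x) < 3) rlang::abort("signal too short for Hjorth parameters")
  v <- stats::var(x)
  if (v == 0) rlang::abort("degenerate (constant) signal")
  sqrt(stats::var(diff(x)) / v)
}

#' @rdname hjorth_mobility
#' @export
hjorth_complexity <- function(x) {
  hjorth_mobility(diff(x)) / hjorth_mobility(x)
}

#' Detrended fluctuation analysis exponent
#'
#' Integrates the mean-centred signal, splits the profile into non-overlapping
#' boxes of each size, removes a per-box linear trend, and returns the slope
#' of log RMS fluctuation against log box size. White noise scales with
#' exponent ~0.5, Brownian paths with ~1.5.
#'
#' @param x Numeric vector.
#' @param box_sizes Integer vector of box sizes; default ~12 sizes log-spaced
#'   in `[4, length(x)/4]`.
#' @return Scaling exponent (slope).
#' @export
dfa_exponent <- function(x, box_sizes = NULL) {
  n <- length(x)
  if (n < 16) rlang::abort("signal too short for DFA")
  if (is.null(box_sizes)) {
    box_sizes <- unique(round(exp(seq(log(4), log(n / 4), length.out = 12))))
  }
  box_sizes <- sort(unique(as.integer(box_sizes)))
  if (length(box_sizes) < 4) rlang::abort("need at least 4 box sizes")
  if (n < 4 * max(box_sizes)) rlang::abort("signal too short for DFA box sizes")
  y <- cumsum(x - mean(x))
  fluct <- vapply(box_sizes, function(b) {
    nbox <- n %/% b
    m <- matrix(y[seq_len(nbox * b)], nrow = b)
    qr_b <- qr(cbind(1, seq_len(b)))
    sqrt(mean(qr.resid(qr_b, m)^2))
  }, numeric(1))
  if (any(fluct <= 0)) rlang::abort("degenerate (constant) signal")
  stats::cov(log(box_sizes), log(fluct)) / stats::var(log(box_sizes))
}

#' Petrosian fractal dimension
#'
#' `log10(n) / (log10(n) + log10(n / (n + 0.4 Nd)))`, where `Nd` counts sign
#' changes in the first difference. A strictly monotone signal has value 1.
#'
#' @param x Numeric vector, length >= 3.
#' @return Scalar >= 1.
#' @export
petrosian_fd <- function(x) {
  n <- length(x)
  if (n < 3) rlang::abort("signal too short")
  d <- diff(x)
  nd <- sum(d[-1] * d[-length(d)] < 0)
  log10(n) / (log10(n) + log10(n / (n + 0.4 * nd)))
}

#' Higuchi fractal dimension
#'
#' Builds Higuchi's averaged normalised curve length `L(k)` for lags
#' `k = 1..k_max` and returns the slope of `log L(k)` against `log(1/k)`.
#' Smooth curves approach 1, white noise approaches 2.
#'
#' @param x Numeric vector.
#' @param k_max Maximum lag (default 8).
#' @return Scalar in (0, 2] in practice.
#' @export
higuchi_fd <- function(x, k_max = 8) {
  n <- length(x)
  if (n < 2 * k_max) rlang::abort("signal too short for k_max")
  lk <- vapply(seq_len(k_max), function(k) {
    lm_k <- vapply(seq_len(k), function(m) {
      idx <- seq.int(m, n, by = k)
      nm <- length(idx) - 1L
      if (nm < 1) return(NA_real_)
      sum(abs(diff(x[idx]))) * (n - 1) / (nm * k) / k
    }, numeric(1))
    mean(lm_k, na.rm = TRUE)
  }, numeric(1))
  if (any(lk <= 0)) rlang::abort("degenerate (constant) signal")
  xk <- log(1 / seq_len(k_max))
  stats::cov(xk, log(lk)) / stats::var(xk)
}

#' Normalised Shannon entropy of a power vector
#'
#' Entropy of `p = power / sum(power)` divided by `log(length(power))`, so a
#' perfectly flat spectrum scores 1 and a single-bin spectrum scores 0.
#'
#' @param power Nonnegative numeric vector.
#' @return Scalar in [0, 1].
#' @export
power_entropy <- function(power) {
  if (any(power < 0)) rlang::abort("negative power")
  s <- sum(power)
  if (s <= 0) rlang::abort("zero total power")
  p <- power / s
  p <- p[p > 0]
  -sum(p * log(p)) / log(length(power))
}

#' Spectral entropy of a signal
#'
#' Normalised Shannon entropy of the Welch power spectral density.
#'
#' @inheritParams welch_psd
#' @return Scalar in [0, 1].
#' @export
spectral_entropy <- function(x, fs = 128, window_len = 128, overlap = 0.5) {
  power_entropy(welch_psd(x, fs, window_len, overlap)$power)
}

# Normalised singular values of the delay-embedding matrix, descending.
.embedding_weights <- function(x, embed_dim = 10, delay = 1) {
  n <- length(x)
  span <- (embed_dim - 1L) * delay
  if (n <= embed_dim * delay) rlang::abort("signal too short for embedding")
  rows <- n - span
  emb <- vapply(seq_len(embed_dim),
                function(j) x[seq.int((j - 1L) * delay + 1L, length.out = rows)],
                numeric(rows))
  ev <- eigen(crossprod(emb), symmetric = TRUE, only.values = TRUE)$values
  sv <- sqrt(pmax(ev, 0))
  if (sum(sv) == 0) rlang::abort("rank-zero embedding (all-zero signal)")
  sv / sum(sv)
}

#' SVD entropy
#'
#' Shannon entropy of the normalised singular values of the delay-embedding
#' matrix, scaled by `log(embed_dim)` to lie in [0, 1]. Low values indicate a
#' signal reconstructable from few components (e.g. a ramp); white noise is
#' near the maximum.
#'
#' @param x Numeric vector.
#' @param embed_dim Embedding dimension (default 10).
#' @param delay Embedding delay in samples (default 1).
#' @return Scalar in [0, 1].
#' @export
svd_entropy <- function(x, embed_dim = 10, delay = 1) {
  w <- .embedding_weights(x, embed_dim, delay)
  w <- w[w > 0]
  -sum(w * log(w)) / log(embed_dim)
}

# Fisher information functional of a normalised singular spectrum.
.fisher_from_weights <- function(w) {
  num <- diff(w)^2
  den <- w[-length(w)]
  sum(ifelse(num == 0 & den == 0, 0, num / den))
}

#' Fisher information of the singular spectrum
#'
#' Sum over adjacent normalised singular values of the squared difference
#' divided by the leading value — a discrete Fisher-information functional of
#' the delay-embedding singular spectrum. A perfectly uniform spectrum gives
#' 0; concentration on one component gives 1.
#'
#' @inheritParams svd_entropy
#' @return Nonnegative scalar.
#' @export
fisher_information <- function(x, embed_dim = 10, delay = 1) {
  .fisher_from_weights(.embedding_weights(x, embed_dim, delay))
}

#' Extraction parameter set
#'
#' All tunable parameters of the feature extractor, with the package defaults:
#' 128-sample Hann Welch segments at 50% overlap, log floor 1e-12, Higuchi
#' `k_max = 8`, ~12 log-spaced DFA box sizes in `[4, n/4]`, delay embedding
#' `(dim, delay) = (10, 1)`.
#'
#' @param welch_window,welch_overlap Welch segment length (samples) / overlap.
#' @param eps Log floor for band powers.
#' @param k_max Higuchi maximum lag.
#' @param dfa_box_sizes DFA box sizes (NULL = log-spaced default).
#' @param embed_dim,delay Delay-embedding parameters for SVD entropy and
#'   Fisher information.
#' @return A named list of class `eeg_feature_params`.
#' @export
feature_params <- function(welch_window = 128, welch_overlap = 0.5,
                           eps = 1e-12, k_max = 8, dfa_box_sizes = NULL,
                           embed_dim = 10, delay = 1) {
  structure(list(welch_window = welch_window, welch_overlap = welch_overlap,
                 eps = eps, k_max = k_max, dfa_box_sizes = dfa_box_sizes,
                 embed_dim = embed_dim, delay = delay),
            class = "eeg_feature_params")
}

# 217 named features for a single 14 x (20 s * fs) window matrix.
.extract_window <- function(mat, layout, bands, params) {
  fs <- layout$sampling_rate
  nch <- length(layout$names)
  stopifnot(nrow(mat) == nch)
  if (!all(is.finite(mat))) rlang::abort("non-finite samples in window")
  psd <- matrix(NA_real_, nch, nrow(bands),
                dimnames = list(layout$names, bands$band))
  nl <- matrix(NA_real_, nch, length(.nonlinear_families),
               dimnames = list(layout$names, .nonlinear_families))
  for (i in seq_len(nch)) {
    x <- mat[i, ]
    spec <- welch_psd(x, fs, params$welch_window, params$welch_overlap)
    psd[i, ] <- vapply(seq_len(nrow(bands)), function(b) {
      band_logpower(spec, bands$f_low[b], bands$f_high[b], params$eps)
    }, numeric(1))
    w <- .embedding_weights(x, params$embed_dim, params$delay)
    wp <- w[w > 0]
    nl[i, ] <- c(
      HM = hjorth_mobility(x),
      HC = hjorth_complexity(x),
      DFA = dfa_exponent(x, params$dfa_box_sizes),
      PFD = petrosian_fd(x),
      HFD = higuchi_fd(x, params$k_max),
      SpecEnt = power_entropy(spec$power),
      svdEnt = -sum(wp * log(wp)) / log(params$embed_dim),
      FI = .fisher_from_weights(w)
    )
  }
  asym <- psd[layout$pairs$left, , drop = FALSE] -
    psd[layout$pairs$right, , drop = FALSE]
  c(as.vector(t(psd)), as.vector(t(asym)), as.vector(t(nl)))
}

#' Extract the 217-feature matrix from a cohort
#'
#' Computes, for every 20-s window, the full feature vector: 70 band
#' log-powers, 35 hemispheric asymmetries and 112 per-channel nonlinear /
#' time-domain descriptors, in the fixed order of [feature_registry()].
#'
#' @param cohort An `eeg_cohort` (or a windows tibble with an `eeg`
#'   list-column of 14 x samples matrices).
#' @param layout An `eeg_layout`; defaults to the cohort's.
#' @param bands Band definitions tibble.
#' @param params An `eeg_feature_params` set.
#' @return A tibble (class `eeg_features`): metadata columns `participant_id`,
#'   `movie_id`, `window_index`, `valence`, `arousal`, `valence_cont`,
#'   `arousal_cont`, followed by 217 feature columns. The registry, band table
#'   and parameters are attached as attributes.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_preset("tiny"))
#' feats <- extract_features(cohort)
#' dim(feats)
#' }
#' @export
extract_features <- function(cohort, layout = NULL,
                             bands = band_definitions(),
                             params = feature_params()) {
  windows <- if (inherits(cohort, "eeg_cohort")) cohort$windows else cohort
  if (is.null(layout)) {
    layout <- if (inherits(cohort, "eeg_cohort")) cohort$layout else channel_layout()
  }
  reg <- feature_registry(layout, bands)
  vals <- purrr::map(windows$eeg, .extract_window,
                     layout = layout, bands = bands, params = params)
  mat <- do.call(rbind, vals)
  colnames(mat) <- reg$name
  if (anyNA(mat)) rlang::abort("feature extraction produced missing values")
  out <- dplyr::bind_cols(
    windows[, c("participant_id", "movie_id", "window_index",
                "valence", "arousal", "valence_cont", "arousal_cont")],
    tibble::as_tibble(mat)
  )
  attr(out, "registry") <- reg
  attr(out, "bands") <- bands
  attr(out, "params") <- params
  class(out) <- c("eeg_features", class(out))
  out
}

#' Feature column names of a feature matrix
#'
#' @param features An `eeg_features` tibble.
#' @return Character vector of the 217 feature column names.
#' @export
feature_names <- function(features) {
  setdiff(names(features),
          c("participant_id", "movie_id", "window_index",
            "valence", "arousal", "valence_cont", "arousal_cont"))
}
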