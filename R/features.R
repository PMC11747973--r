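#' Feature sets
#'
#' The stimulus representation `s(t)`: a time-by-feature matrix at the EEG
#' sampling rate, with a per-column flag marking discrete (sparse 0/1 event
#' marker) columns versus continuous ones. Discrete columns must contain
#' only 0 and 1.
#'
#' @param data Numeric matrix (or vector, treated as one column).
#' @param rate Sampling rate in Hz.
#' @param names Column labels.
#' @param discrete Logical per column; `TRUE` marks a binary event column.
#' @return An object of class `feature_set`.
#' @export
feature_set <- function(data, rate, names = NULL, discrete = NULL) {
  data <- as.matrix(data)
  stopifnot(rate > 0, nrow(data) > 0)
  if (any(!is.finite(data))) abort("feature values must be finite")
  names <- names %||% colnames(data) %||%
    sprintf("f%02d", seq_len(ncol(data)))
  discrete <- discrete %||% apply(data, 2, is_binary01)
  stopifnot(length(names) == ncol(data), length(discrete) == ncol(data))
  for (j in which(discrete)) {
    if (!is_binary01(data[, j])) {
      abort(sprintf("discrete column '%s' contains values other than 0/1",
                    names[j]))
    }
  }
  colnames(data) <- names
  structure(list(data = data, rate = rate, names = names,
                 discrete = as.logical(discrete)),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d samples x %d features @ %g Hz\n",
              nrow(x$data), ncol(x$data), x$rate))
  cat("  ", paste0(x$names, ifelse(x$discrete, " [d]", ""),
                   collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.feature_set <- function(x) dim(x$data)

#' @rdname feature_set
#' @param x A `feature_set`.
#' @param ... Unused.
#' @method tidy feature_set
#' @export
tidy.feature_set <- function(x, ...) {
  tibble::as_tibble(x$data) |>
    dplyr::mutate(time_s = (dplyr::row_number() - 1) / x$rate,
                  .before = 1) |>
    tidyr::pivot_longer(-"time_s", names_to = "feature",
                        values_to = "value")
}

as_feature_matrix <- function(x) {
  if (inherits(x, "feature_set")) x$data else as.matrix(x)
}

#' Default feature-extraction configuration
#'
#' Parameters of the acoustic feature pipeline. `novelty_window` /
#' `novelty_hop` are in audio samples; `onset_threshold` is in novelty units
#' and was calibrated on the synthetic tone bank so that at least 95% of
#' true event onsets are recovered within +/- 50 ms (see the methods
#' vignette).
#'
#' @param novelty_window Hann energy window length (audio samples).
#' @param novelty_hop Hop between energy frames (audio samples).
#' @param gamma Logarithmic compression factor in `log(1 + gamma * x)`.
#' @param onset_threshold Peak-picking threshold on the novelty curve.
#' @param butter_order,butter_cutoff_hz Envelope low-pass filter settings.
#' @param n_mels Number of mel bands.
#' @param eeg_rate_hz Output (EEG) sampling rate in Hz.
#' @param power_compression_exponent Pointwise exponent applied to the power
#'   envelope (default `log10(2)`, close to a square root).
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(novelty_window = 2048, novelty_hop = 128,
                           gamma = 10, onset_threshold = 0.05,
                           butter_order = 3, butter_cutoff_hz = 30,
                           n_mels = 40, eeg_rate_hz = 100,
                           power_compression_exponent = log10(2)) {
  cfg <- list(novelty_window = novelty_window, novelty_hop = novelty_hop,
              gamma = gamma, onset_threshold = onset_threshold,
              butter_order = butter_order,
              butter_cutoff_hz = butter_cutoff_hz, n_mels = n_mels,
              eeg_rate_hz = eeg_rate_hz,
              power_compression_exponent = power_compression_exponent)
  if (any(unlist(cfg) <= 0)) abort("all feature_config values must be > 0")
  if (novelty_hop > novelty_window) {
    abort("novelty_hop must not exceed novelty_window")
  }
  structure(cfg, class = c("feature_config", "list"))
}

check_mono <- function(audio) {
  if (is.matrix(audio$samples) || !is.null(dim(audio$samples))) {
    abort("audio must be mono; average the channels first (see read_wav)")
  }
  invisible(audio)
}

n_eeg_samples <- function(n_audio, audio_rate, eeg_rate) {
  round(n_audio / audio_rate * eeg_rate)
}

# Interpolate a frame-rate curve onto the EEG sample grid (sample k of the
# output corresponds to time k / eeg_rate; frame i to time (i-1) * hop/rate).
to_eeg_grid <- function(x, times_s, eeg_rate, n_out) {
  t_out <- (seq_len(n_out) - 1) / eeg_rate
  approx(times_s, x, xout = t_out, rule = 2)$y
}

#' Energy novelty curve of a soundscape
#'
#' The spectral-energy onset detector front end: the waveform is squared and
#' smoothed with a Hann window (local energy at the hop rate), compressed as
#' `log(1 + gamma * x)`, differenced, smoothed again (Hann at one quarter of
#' the energy window, in frames), half-wave rectified, and brought onto the
#' EEG sample grid. Peaks of the result mark transient increases of sound
#' energy.
#'
#' @param audio A mono [audio_track()]; its rate must be at least twice the
#'   EEG rate.
#' @param config A [feature_config()].
#' @return A one-column continuous `feature_set` named `"novelty"` at
#'   `config$eeg_rate_hz`.
#' @export
energy_novelty <- function(audio, config = feature_config()) {
  check_mono(audio)
  if (audio$rate < 2 * config$eeg_rate_hz) {
    abort("audio rate must be at least twice the EEG rate")
  }
  x <- audio$samples
  w <- hann_window(min(config$novelty_window, length(x)), normalize = TRUE)
  energy <- fft_conv_same(x^2, w)
  idx <- seq(1, length(x), by = config$novelty_hop)
  frames <- pmax(energy[idx], 0)
  frame_t <- (idx - 1) / audio$rate
  compressed <- log(1 + config$gamma * frames)
  d <- c(0, diff(compressed))
  sm_len <- max(3L, round(config$novelty_window / config$novelty_hop / 4))
  sm_len <- sm_len + (sm_len + 1L) %% 2L   # force odd for symmetric smoothing
  d <- fft_conv_same(d, hann_window(sm_len, normalize = TRUE))
  novelty <- pmax(d, 0)
  n_out <- n_eeg_samples(length(x), audio$rate, config$eeg_rate_hz)
  out <- pmax(to_eeg_grid(novelty, frame_t, config$eeg_rate_hz, n_out), 0)
  feature_set(out, config$eeg_rate_hz, names = "novelty", discrete = FALSE)
}

#' Detect acoustic onsets by thresholded peak picking
#'
#' Marks a 1 exactly at every local maximum of the novelty curve that
#' exceeds `threshold` (plateaus resolve to their first sample); all other
#' samples are 0.
#'
#' @param novelty A one-column `feature_set` (see [energy_novelty()]) or a
#'   numeric vector plus `rate`.
#' @param threshold Positive threshold in novelty units.
#' @param rate Required when `novelty` is a bare vector.
#' @return A one-column discrete `feature_set` named `"onsets"`.
#' @export
detect_onsets <- function(novelty, threshold, rate = NULL) {
  stopifnot(threshold > 0)
  if (inherits(novelty, "feature_set")) {
    rate <- novelty$rate
    v <- as.numeric(novelty$data[, 1])
  } else {
    if (is.null(rate)) abort("`rate` is required for a bare novelty vector")
    v <- as.numeric(novelty)
  }
  out <- rep(0, length(v))
  out[local_maxima(v) & v > threshold] <- 1
  feature_set(out, rate, names = "onsets", discrete = TRUE)
}

# Strict local maxima; plateau runs count once, at their first sample.
local_maxima <- function(v) {
  n <- length(v)
  if (n == 0) return(logical(0))
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  left <- c(-Inf, r$values[-k])
  right <- c(r$values[-1], -Inf)
  is_max <- r$values > left & r$values > right
  out <- logical(n)
  out[starts[is_max]] <- TRUE
  out
}

#' Hilbert envelope of a soundscape
#'
#' Magnitude of the analytic signal, smoothed with a zero-phase third-order
#' Butterworth low-pass at 30 Hz and downsampled to the EEG rate (the
#' low-pass doubles as the anti-aliasing filter; the EEG Nyquist of 50 Hz
#' lies above the cutoff).
#'
#' @inheritParams energy_novelty
#' @return A one-column continuous `feature_set` named `"envelope"`.
#' @export
hilbert_envelope <- function(audio, config = feature_config()) {
  check_mono(audio)
  x <- audio$samples
  warmup <- 3 * (2 * config$butter_order + 1)
  if (length(x) < max(warmup, 8)) {
    abort("audio is shorter than the low-pass filter warm-up")
  }
  env <- Mod(analytic_signal(x))
  bf <- signal::butter(config$butter_order,
                       config$butter_cutoff_hz / (audio$rate / 2),
                       type = "low")
  env <- as.numeric(signal::filtfilt(bf, env))
  n_out <- n_eeg_samples(length(x), audio$rate, config$eeg_rate_hz)
  t_in <- (seq_along(env) - 1) / audio$rate
  out <- to_eeg_grid(env, t_in, config$eeg_rate_hz, n_out)
  feature_set(out, config$eeg_rate_hz, names = "envelope", discrete = FALSE)
}

# Analytic signal via the frequency-domain Hilbert transformer.
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' Compressed power envelope
#'
#' Squares the waveform, block-averages it down to the EEG rate (moving
#' average over non-overlapping windows of `audio_rate / eeg_rate` samples)
#' and compresses pointwise with exponent
#' `config$power_compression_exponent` (default `log10(2)`, close to a
#' square root; the exponent 0.5 gives exactly the RMS envelope).
#'
#' @inheritParams energy_novelty
#' @return A one-column continuous `feature_set` named `"power_envelope"`.
#' @export
power_envelope <- function(audio, config = feature_config()) {
  check_mono(audio)
  ratio <- audio$rate / config$eeg_rate_hz
  if (abs(ratio - round(ratio)) > 1e-9) {
    abort("audio rate must be an integer multiple of the EEG rate")
  }
  ratio <- as.integer(round(ratio))
  x <- audio$samples
  n_out <- n_eeg_samples(length(x), audio$rate, config$eeg_rate_hz)
  n_full <- n_out * ratio
  xx <- c(x, rep(0, max(0, n_full - length(x))))[seq_len(n_full)]
  pow <- colMeans(matrix(xx^2, nrow = ratio))
  out <- pow^config$power_compression_exponent
  feature_set(out, config$eeg_rate_hz, names = "power_envelope",
              discrete = FALSE)
}

#' Mel-spectrogram at the EEG frame rate
#'
#' Short-time power spectra (25 ms Hann windows, hops of `1 / eeg_rate`)
#' mapped through a bank of `n_mels` triangular filters spaced on the mel
#' scale between 0 Hz and Nyquist; frames are aligned so that row k
#' corresponds to time k / eeg_rate, and the output is trimmed or
#' zero-padded to the EEG length.
#'
#' @inheritParams energy_novelty
#' @return A continuous `feature_set` with `n_mels` columns (`mel_01` ...)
#'   carrying the band center frequencies in attribute `center_freq_hz`.
#' @export
mel_spectrogram <- function(audio, config = feature_config()) {
  check_mono(audio)
  x <- audio$samples
  rate <- audio$rate
  n_win <- max(4L, round(0.025 * rate))
  hop <- rate / config$eeg_rate_hz
  if (abs(hop - round(hop)) > 1e-9) {
    abort("audio rate must be an integer multiple of the EEG rate")
  }
  hop <- as.integer(round(hop))
  nfft <- stats::nextn(n_win, 2)
  n_bins <- nfft %/% 2 + 1L
  if (config$n_mels > n_bins) {
    abort("n_mels exceeds the number of FFT bins for this window")
  }
  fb <- mel_filterbank(config$n_mels, nfft, rate)
  n_out <- n_eeg_samples(length(x), rate, config$eeg_rate_hz)
  w <- hann_window(n_win)
  half <- n_win %/% 2
  xp <- c(rep(0, half), x, rep(0, n_win))
  out <- matrix(0, n_out, config$n_mels)
  for (i in seq_len(n_out)) {
    i0 <- (i - 1L) * hop + 1L           # frame centered on time (i-1)/eeg_rate
    seg <- xp[i0:(i0 + n_win - 1L)] * w
    spec <- Mod(fft(c(seg, rep(0, nfft - n_win))))[seq_len(n_bins)]^2
    out[i, ] <- as.numeric(spec %*% fb$weights)
  }
  fs <- feature_set(out, config$eeg_rate_hz,
                    names = sprintf("mel_%02d", seq_len(config$n_mels)),
                    discrete = rep(FALSE, config$n_mels))
  attr(fs, "center_freq_hz") <- fb$center_freq_hz
  fs
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular mel filterbank, bins x filters.
mel_filterbank <- function(n_mels, nfft, rate) {
  n_bins <- nfft %/% 2 + 1L
  f_bins <- (seq_len(n_bins) - 1) * rate / nfft
  edges <- mel_to_hz(seq(hz_to_mel(0), hz_to_mel(rate / 2),
                         length.out = n_mels + 2))
  weights <- matrix(0, n_bins, n_mels)
  for (j in seq_len(n_mels)) {
    lo <- edges[j]; ce <- edges[j + 1]; hi <- edges[j + 2]
    up <- (f_bins - lo) / (ce - lo)
    down <- (hi - f_bins) / (hi - ce)
    weights[, j] <- pmax(0, pmin(up, down))
  }
  list(weights = weights, center_freq_hz = edges[2:(n_mels + 1)])
}

#' Binary sound-identity / condition marker features
#'
#' One binary column per event category (or per category-condition pair
#' when `condition_split = TRUE`), with a single 1 at the sample nearest
#' each onset and zeros elsewhere, zero-padded to `n_samples`.
#'
#' @param events An [event_table()].
#' @param n_samples Output length in samples.
#' @param rate Sampling rate in Hz; all onsets must satisfy
#'   `onset_s < n_samples / rate`.
#' @param categories Categories to include (default: all present, in order
#'   of first appearance).
#' @param condition_split If `TRUE`, split each category into one column per
#'   condition (`<category>_narrow`, `<category>_wide`).
#' @return A discrete `feature_set`.
#' @export
events_to_markers <- function(events, n_samples, rate,
                              categories = NULL, condition_split = FALSE) {
  validate_event_table(events)
  categories <- categories %||% unique(events$category)
  if (length(categories) == 0) abort("no categories requested")
  if (nrow(events) > 0 && any(events$onset_s >= n_samples / rate)) {
    abort("all event onsets must fall before n_samples / rate")
  }
  sel <- events[events$category %in% categories, , drop = FALSE]
  if (condition_split) {
    if (any(is.na(sel$condition))) {
      abort("condition_split requires a condition label on every event")
    }
    keys <- as.vector(t(outer(categories, c("narrow", "wide"), paste,
                              sep = "_")))
    ev_key <- paste(sel$category, sel$condition, sep = "_")
  } else {
    keys <- categories
    ev_key <- sel$category
  }
  out <- matrix(0, n_samples, length(keys))
  for (j in seq_along(keys)) {
    idx <- time_to_index(sel$onset_s[ev_key == keys[j]], rate)
    if (anyDuplicated(idx)) {
      abort(sprintf(
        "two '%s' events map to the same sample at %g Hz (resolution limit)",
        keys[j], rate))
    }
    out[idx, j] <- 1
  }
  feature_set(out, rate, names = keys,
              discrete = rep(TRUE, length(keys)))
}

#' Combine feature sets onto a common [0, 1] scale
#'
#' Concatenates the columns of several feature sets. Non-binary columns are
#' min-max normalized to `[0, 1]` (a constant column degenerates to all
#' zeros); binary marker columns are left untouched so that every column of
#' a mixed model shares the scale of the discrete markers. Discreteness
#' flags are preserved.
#'
#' @param ... `feature_set` objects sharing rate and length.
#' @return A `feature_set`.
#' @export
combine_features <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) >= 1)
  rates <- vapply(sets, function(s) s$rate, numeric(1))
  lens <- vapply(sets, function(s) nrow(s$data), integer(1))
  if (length(unique(rates)) != 1) abort("feature sets differ in rate")
  if (length(unique(lens)) != 1) abort("feature sets differ in length")
  data <- do.call(cbind, lapply(sets, function(s) s$data))
  discrete <- unlist(lapply(sets, function(s) s$discrete))
  nms <- make.unique(unlist(lapply(sets, function(s) s$names)))
  for (j in which(!discrete)) {
    rng <- range(data[, j])
    data[, j] <- if (diff(rng) == 0) 0 else (data[, j] - rng[1]) / diff(rng)
  }
  feature_set(data, rates[1], names = nms, discrete = discrete)
}
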