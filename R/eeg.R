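#' EEG recordings
#'
#' A time-by-channel matrix of neural samples `r(t, c)` with its sampling
#' rate and channel names.
#'
#' @param data Numeric matrix, time in rows, channels in columns.
#' @param rate Sampling rate in Hz.
#' @param channel_names Optional channel labels.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, rate, channel_names = NULL) {
  data <- as.matrix(data)
  stopifnot(nrow(data) > 0, ncol(data) >= 1, rate > 0)
  if (any(!is.finite(data))) abort("EEG samples must be finite")
  channel_names <- channel_names %||% sprintf("ch%02d", seq_len(ncol(data)))
  stopifnot(length(channel_names) == ncol(data))
  colnames(data) <- channel_names
  structure(list(data = data, rate = rate, channel_names = channel_names),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d samples x %d channels @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$rate, nrow(x$data) / x$rate))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

#' @rdname eeg_recording
#' @param x An `eeg_recording`.
#' @param ... Unused.
#' @method tidy eeg_recording
#' @export
tidy.eeg_recording <- function(x, ...) {
  tibble::as_tibble(x$data) |>
    dplyr::mutate(time_s = (dplyr::row_number() - 1) / x$rate,
                  .before = 1) |>
    tidyr::pivot_longer(-"time_s", names_to = "channel",
                        values_to = "value")
}

# Clean event-related signal: kernel placed at every event onset (identical
# response per trial unless per-trial amplitude jitter is requested).
event_kernel_signal <- function(events, kernel, n_samples, rate,
                                amplitudes = NULL) {
  x <- rep(0, n_samples)
  if (nrow(events) == 0) return(x)
  amplitudes <- amplitudes %||% rep(1, nrow(events))
  klen <- length(kernel$amplitude)
  for (i in seq_len(nrow(events))) {
    i0 <- time_to_index(events$onset_s[i], rate)
    i1 <- min(i0 + klen - 1L, n_samples)
    if (i1 >= i0) {
      x[i0:i1] <- x[i0:i1] + amplitudes[i] * kernel$amplitude[seq_len(i1 - i0 + 1L)]
    }
  }
  x
}

# Closed-form E|k + n| for n ~ N(0, sigma^2).
expected_abs_normal <- function(k, sigma) {
  sigma * sqrt(2 / pi) * exp(-k^2 / (2 * sigma^2)) +
    abs(k) * (1 - 2 * pnorm(-abs(k) / sigma))
}

#' Noise level for a target single-trial SNR
#'
#' Solves analytically for the pink-noise standard deviation implementing a
#' target SNR under the single-trial convention of [estimate_trial_snr()]
#' (mean absolute response over `[0, 0.5]` s divided by the baseline-window
#' standard deviation, in dB):
#' `sigma = mean|kernel| / (c * 10^(snr_db / db_factor))`, where `c` is the
#' theoretical within-window standard deviation of the 1/f noise relative
#' to its marginal sd (a short baseline window excludes the dominant
#' low-frequency power of pink noise, so `c` is well below 1). The target
#' refers to the clean kernel amplitude; the empirical estimator agrees
#' with it at high SNR but saturates near `+20*log10(0.8/c)` dB at strong
#' noise, because its numerator is then dominated by `E|noise|`. Targets
#' below that floor are therefore nominal labels of noise strength, not
#' attainable estimator readings (see [estimator_snr_floor()] and the
#' methods vignette).
#'
#' @param kernel An `erp_kernel` at the EEG rate.
#' @param snr_db Target SNR in dB.
#' @param n_samples Recording length in samples (fixes the pink-noise
#'   spectrum's lowest frequency).
#' @param rate EEG sampling rate in Hz.
#' @param baseline_window,response_window Estimator windows in seconds,
#'   matching [estimate_trial_snr()].
#' @param db_factor 20 for an amplitude-ratio dB convention (default), 10
#'   for a power convention.
#' @return List with `sigma` (noise sd), `attenuation` (`c`) and
#'   `kernel_mean_abs`.
#' @export
calibrate_noise_sd <- function(kernel, snr_db, n_samples, rate,
                               baseline_window = c(-0.1, -0.01),
                               response_window = c(0, 0.5),
                               db_factor = 20) {
  stopifnot(is.finite(snr_db))
  ridx <- round(response_window[1] * rate):round(response_window[2] * rate)
  k <- rep(0, length(ridx))
  kidx <- ridx + 1L
  ok <- kidx >= 1 & kidx <= length(kernel$amplitude)
  k[ok] <- kernel$amplitude[kidx[ok]]
  m <- mean(abs(k))
  if (m == 0) abort("kernel is identically zero; SNR is undefined")
  w <- length(round(baseline_window[1] * rate):round(baseline_window[2] * rate))
  rho <- pink_autocovariance(n_samples)
  c_att <- sqrt(expected_window_variance(rho, w))
  sigma <- m / (c_att * 10^(snr_db / db_factor))
  list(sigma = sigma, attenuation = c_att, kernel_mean_abs = m)
}

#' Saturation floor of the single-trial SNR estimator
#'
#' Expected reading of [estimate_trial_snr()] in the strong-noise limit,
#' where the response-window numerator is pure noise: the estimator tends
#' to `db_factor * log10(sqrt(2/pi) / c)` with `c` the baseline attenuation
#' factor of [calibrate_noise_sd()]. Readings below this floor are not
#' attainable for any noise gain, which is why low-SNR sweep levels are
#' nominal.
#'
#' @inheritParams calibrate_noise_sd
#' @return Floor in dB.
#' @export
estimator_snr_floor <- function(n_samples, rate,
                                baseline_window = c(-0.1, -0.01),
                                db_factor = 20) {
  w <- length(round(baseline_window[1] * rate):round(baseline_window[2] * rate))
  rho <- pink_autocovariance(n_samples)
  c_att <- sqrt(expected_window_variance(rho, w))
  db_factor * log10(sqrt(2 / pi) / c_att)
}

#' Synthesize an EEG recording from an event train
#'
#' The clean signal is the sum over events of a response kernel placed at
#' each onset -- the identical-response-per-trial assumption of the
#' ERP-in-pink-noise simulation. Independent 1/f pink noise is added per
#' channel, scaled via [calibrate_noise_sd()] so that the single-trial SNR
#' approximates `snr_db` (exact matching is only possible above the
#' estimator's noise floor; below it the noise scale follows the
#' amplitude-ratio definition). `snr_db = Inf` adds no noise.
#'
#' @param events An [event_table()].
#' @param kernel An `erp_kernel`; its rate must equal `eeg_rate`.
#' @param snr_db Target SNR in dB (may be `Inf`; must not be `NA`/`NaN`).
#' @param n_channels Number of channels.
#' @param eeg_rate Sampling rate in Hz.
#' @param seed Integer seed (noise and jitter are pure functions of it).
#' @param duration_s Recording length in seconds; defaults to the last event
#'   onset plus the kernel span.
#' @param amplitude_jitter_sd Per-trial multiplicative amplitude jitter
#'   (standard deviation around 1); 0 (default) reproduces identical
#'   responses per trial.
#' @param db_factor dB convention passed to [calibrate_noise_sd()].
#' @return An [eeg_recording()] with attributes `sigma_noise` and
#'   `clean_signal`.
#' @export
synthesize_eeg <- function(events, kernel, snr_db, n_channels = 22,
                           eeg_rate = 100, seed, duration_s = NULL,
                           amplitude_jitter_sd = 0, db_factor = 20) {
  validate_event_table(events)
  if (is.na(snr_db)) abort("`snr_db` must be finite or Inf")
  if (abs(kernel$rate - eeg_rate) > 1e-9) {
    abort("kernel rate must equal `eeg_rate`")
  }
  if (missing(seed)) abort("`seed` is required: synthesis is stochastic")
  span <- max(kernel$lag_s)
  duration_s <- duration_s %||%
    (if (nrow(events) > 0) max(events$onset_s) + span else 1)
  if (nrow(events) > 0 && any(events$onset_s >= duration_s)) {
    abort("all event onsets must fall within `duration_s`")
  }
  n <- round(duration_s * eeg_rate)
  seeds <- derive_seeds(seed, 2)
  amplitudes <- NULL
  if (amplitude_jitter_sd > 0 && nrow(events) > 0) {
    amplitudes <- withr::with_seed(seeds[1],
                                   rnorm(nrow(events), 1, amplitude_jitter_sd))
  }
  clean <- event_kernel_signal(events, kernel, n, eeg_rate, amplitudes)
  data <- matrix(clean, n, n_channels)
  sigma <- 0
  if (is.finite(snr_db)) {
    cal <- calibrate_noise_sd(kernel, snr_db, n, eeg_rate,
                              db_factor = db_factor)
    sigma <- cal$sigma
    data <- data + sigma * pink_noise(n, n_channels, seed = seeds[2])
  }
  rec <- eeg_recording(data, eeg_rate)
  attr(rec, "sigma_noise") <- sigma
  attr(rec, "clean_signal") <- clean
  rec
}
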