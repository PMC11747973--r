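#' Single-trial SNR estimate around events
#'
#' For every event, takes the standard deviation of a pre-stimulus baseline
#' window (default `[-0.1, -0.01]` s) and the mean absolute value of the
#' response window (default `[0, 0.5]` s), per channel, and converts their
#' ratio to dB (`20 * log10`, an amplitude convention; set `db_factor = 10`
#' for a power convention). The per-trial value is the channel average of
#' the per-channel dB estimates. Events whose windows fall outside the
#' recording are skipped with a notice. An all-zero response window yields
#' `-Inf`, flagged as undefined.
#'
#' @param eeg An [eeg_recording()].
#' @param events An [event_table()].
#' @param baseline_window,response_window Windows in seconds relative to
#'   each onset.
#' @param db_factor 20 (amplitude, default) or 10 (power).
#' @return A tibble with `event`, `onset_s`, `snr_db` and logical
#'   `defined`.
#' @export
estimate_trial_snr <- function(eeg, events,
                               baseline_window = c(-0.1, -0.01),
                               response_window = c(0, 0.5),
                               db_factor = 20) {
  stopifnot(inherits(eeg, "eeg_recording"))
  validate_event_table(events)
  rate <- eeg$rate
  n <- nrow(eeg$data)
  b_off <- round(baseline_window[1] * rate):round(baseline_window[2] * rate)
  r_off <- round(response_window[1] * rate):round(response_window[2] * rate)
  out <- vector("list", nrow(events))
  skipped <- 0L
  for (i in seq_len(nrow(events))) {
    e <- time_to_index(events$onset_s[i], rate)
    bi <- e + b_off
    ri <- e + r_off
    if (min(bi, ri) < 1 || max(bi, ri) > n) {
      skipped <- skipped + 1L
      next
    }
    snr_ch <- vapply(seq_len(ncol(eeg$data)), function(ch) {
      sb <- sd(eeg$data[bi, ch])
      ma <- mean(abs(eeg$data[ri, ch]))
      if (sb == 0) return(NaN)
      db_factor * log10(ma / sb)
    }, numeric(1))
    val <- mean(snr_ch)
    out[[i]] <- tibble::tibble(event = i, onset_s = events$onset_s[i],
                               snr_db = val,
                               defined = is.finite(val))
  }
  if (skipped > 0) {
    inform(sprintf("%d event(s) too close to the recording edge: skipped",
                   skipped))
  }
  dplyr::bind_rows(out)
}

#' ERP-in-pink-noise SNR sweep
#'
#' The simulation protocol for judging whether high masked prediction
#' scores are plausible: for every SNR on the grid, place `n_events`
#' triphasic ERP kernels at random (minimum-gap) onsets in `duration_s`
#' seconds of data, add 1/f pink noise, run the standard cross-validated
#' onset-TRF protocol, and score held-out folds both over the whole segment
#' and restricted to the explainable-sample mask. Results are averaged over
#' replicates (distinct seeds).
#'
#' @param snr_grid_db SNR grid in dB, sorted ascending (default -30 to 10
#'   in 5 dB steps).
#' @param n_replicates Independent replicates per SNR (default 10).
#' @param duration_s,n_events,min_gap_s Event-train geometry (defaults: 10
#'   minutes, 396 events, 0.6 s minimum gap).
#' @param n_channels,eeg_rate Recording geometry.
#' @param kernel Response kernel (default [make_triphasic_kernel()] at
#'   `eeg_rate`).
#' @param seed Integer seed; per-replicate seeds derive from it.
#' @inheritParams trf_crossval
#' @return An `snr_curve` tibble with columns `snr_db`, `r_whole`,
#'   `r_masked`, `sd_whole`, `sd_masked`, `proportion_explainable`,
#'   `n_replicates`. The per-replicate fold scores are kept in attribute
#'   `replicates`.
#' @export
run_snr_sweep <- function(snr_grid_db = seq(-30, 10, by = 5),
                          n_replicates = 10,
                          duration_s = 600, n_events = 396,
                          min_gap_s = 0.6, n_channels = 22, eeg_rate = 100,
                          kernel = NULL, n_segments = 6,
                          lambda_grid = default_lambda_grid(),
                          tmin_ms = -100, tmax_ms = 500, seed) {
  if (missing(seed)) abort("`seed` is required")
  if (length(snr_grid_db) == 0) abort("SNR grid is empty")
  snr_grid_db <- sort(snr_grid_db)
  kernel <- kernel %||% make_triphasic_kernel(eeg_rate)
  seeds <- matrix(derive_seeds(seed, length(snr_grid_db) * n_replicates),
                  nrow = length(snr_grid_db))
  reps <- vector("list", length(snr_grid_db) * n_replicates)
  k <- 0L
  for (si in seq_along(snr_grid_db)) {
    for (rep_i in seq_len(n_replicates)) {
      k <- k + 1L
      reps[[k]] <- tryCatch(
        snr_sweep_one(snr_grid_db[si], rep_i, seeds[si, rep_i], duration_s,
                      n_events, min_gap_s, n_channels, eeg_rate, kernel,
                      n_segments, lambda_grid, tmin_ms, tmax_ms),
        error = function(e) {
          abort(sprintf("sweep failed at SNR %g dB, replicate %d: %s",
                        snr_grid_db[si], rep_i, conditionMessage(e)))
        })
    }
  }
  reps <- dplyr::bind_rows(reps)
  curve <- reps |>
    dplyr::summarise(
      r_whole = mean(.data$score), r_masked = mean(.data$score_masked),
      sd_whole = sd(.data$score), sd_masked = sd(.data$score_masked),
      proportion_explainable = mean(.data$proportion),
      n_replicates = dplyr::n_distinct(.data$replicate),
      .by = "snr_db")
  curve <- dplyr::arrange(curve, .data$snr_db)
  class(curve) <- c("snr_curve", class(curve))
  attr(curve, "replicates") <- reps
  curve
}

snr_sweep_one <- function(snr_db, rep_i, seed, duration_s, n_events,
                          min_gap_s, n_channels, eeg_rate, kernel,
                          n_segments, lambda_grid, tmin_ms, tmax_ms) {
  sub_seeds <- derive_seeds(seed, 2)
  events <- generate_event_train(duration_s, n_events, min_gap_s,
                                 categories = "tone", seed = sub_seeds[1])
  eeg <- synthesize_eeg(events, kernel, snr_db, n_channels, eeg_rate,
                        seed = sub_seeds[2], duration_s = duration_s)
  onsets <- events_to_markers(events, nrow(eeg$data), eeg_rate)
  mask <- explainable_mask(onsets, tmin_ms, tmax_ms)
  cvr <- trf_crossval(onsets, eeg, n_segments = n_segments,
                      lambda_grid = lambda_grid, tmin_ms = tmin_ms,
                      tmax_ms = tmax_ms, mask = mask$mask)
  dplyr::mutate(cvr$scores, snr_db = snr_db, replicate = rep_i,
                proportion = mask$proportion, .before = 1) |>
    dplyr::summarise(score = mean(.data$score),
                     score_masked = mean(.data$score_masked),
                     proportion = .data$proportion[1],
                     .by = c("snr_db", "replicate"))
}
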