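#' Audio tracks
#'
#' A mono waveform with its sampling rate. Amplitudes are dimensionless and
#' nominally within `[-1, 1]`.
#'
#' @param samples Numeric vector of amplitudes.
#' @param rate Sampling rate in Hz.
#' @return An object of class `audio_track`.
#' @export
audio_track <- function(samples, rate) {
  stopifnot(is.numeric(samples), rate > 0)
  if (any(!is.finite(samples))) abort("audio samples must be finite")
  structure(list(samples = as.numeric(samples), rate = rate),
            class = "audio_track")
}

#' @export
print.audio_track <- function(x, ...) {
  cat(sprintf("<audio_track> %d samples @ %g Hz (%.2f s)\n",
              length(x$samples), x$rate, length(x$samples) / x$rate))
  invisible(x)
}

#' @export
length.audio_track <- function(x) length(x$samples)

rms <- function(x) sqrt(mean(x^2))

#' Build a bank of pure-tone waveforms for the soundscape categories
#'
#' The defaults emulate the study conditions: an 800 Hz / 60 ms beep, a
#' 1000 Hz / 200 ms monitor-like "irrelevant" tone and a 600 Hz / 200 ms
#' amplitude-modulated alarm. Amplitudes deliberately differ across tones so
#' that the RMS matching done by [render_soundscape()] is observable. Each
#' tone carries a 5 ms cosine on/off ramp to avoid clicks.
#'
#' @param rate Sampling rate in Hz.
#' @param categories Category labels to build tones for.
#' @return Named list of numeric waveforms at `rate`.
#' @export
tone_bank <- function(rate,
                      categories = c("beep", "irrelevant", "alarm")) {
  spec <- list(
    beep       = list(freq = 800,  dur = 0.06, amp = 0.9, am = 0),
    irrelevant = list(freq = 1000, dur = 0.20, amp = 0.3, am = 0),
    alarm      = list(freq = 600,  dur = 0.20, amp = 0.6, am = 8)
  )
  unknown <- setdiff(categories, names(spec))
  tones <- lapply(categories, function(cat) {
    p <- spec[[cat]]
    if (is.null(p)) p <- list(freq = 750, dur = 0.15, amp = 0.5, am = 0)
    t <- seq(0, p$dur - 1 / rate, by = 1 / rate)
    x <- p$amp * sin(2 * pi * p$freq * t)
    if (p$am > 0) x <- x * (0.6 + 0.4 * sin(2 * pi * p$am * t))
    nr <- max(2L, round(0.005 * rate))
    ramp <- 0.5 - 0.5 * cos(pi * (seq_len(nr) - 1) / (nr - 1))
    x[seq_len(nr)] <- x[seq_len(nr)] * ramp
    x[(length(x) - nr + 1):length(x)] <-
      x[(length(x) - nr + 1):length(x)] * rev(ramp)
    x
  })
  names(tones) <- categories
  tones
}

#' Render an annotated event train into a soundscape waveform
#'
#' Every tone in the bank is first RMS-normalized to the average RMS of all
#' bank tones (loudness matching), then placed at its event onset;
#' overlapping tones sum. Samples outside every event extent are exactly
#' zero.
#'
#' @param events An [event_table()].
#' @param bank Named list of waveforms (see [tone_bank()]); every event
#'   category must have an entry.
#' @param rate Output sampling rate in Hz; bank waveforms are assumed to be
#'   at this rate.
#' @param duration_s Output duration; defaults to the latest event extent
#'   (or 1 s for an empty table).
#' @return An [audio_track()].
#' @export
render_soundscape <- function(events, bank, rate, duration_s = NULL) {
  stopifnot(rate > 0)
  validate_event_table(events)
  if (nrow(events) == 0) {
    n <- round((duration_s %||% 1) * rate)
    return(audio_track(rep(0, n), rate))
  }
  missing_cat <- setdiff(unique(events$category), names(bank))
  if (length(missing_cat) > 0) {
    abort(paste0("no tone in bank for category: ",
                 paste(missing_cat, collapse = ", ")))
  }
  target_rms <- mean(vapply(bank, rms, numeric(1)))
  bank_norm <- lapply(bank, function(x) {
    r <- rms(x)
    if (r == 0) x else x * (target_rms / r)
  })
  extents <- events$onset_s +
    vapply(bank_norm[events$category], length, integer(1)) / rate
  n <- round((duration_s %||% max(extents)) * rate)
  out <- rep(0, n)
  for (i in seq_len(nrow(events))) {
    tone <- bank_norm[[events$category[i]]]
    i0 <- time_to_index(events$onset_s[i], rate)
    i1 <- min(i0 + length(tone) - 1L, n)
    if (i1 >= i0) out[i0:i1] <- out[i0:i1] + tone[seq_len(i1 - i0 + 1L)]
  }
  audio_track(out, rate)
}
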