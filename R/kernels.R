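#' Triphasic P1-N1-P2 response kernels
#'
#' Builds a smooth triphasic auditory-evoked-response kernel as the sum of
#' three Gaussian bumps at the requested peak latencies, with
#' sign-alternating amplitudes (+, -, +) by default. A short cosine taper
#' pins the kernel to exactly zero at lag 0 and at the kernel end; the taper
#' is kept away from the peaks so the requested extrema are preserved.
#'
#' @param rate Sampling rate in Hz.
#' @param peak_latencies_s Three strictly increasing latencies within
#'   `[0, span_s]` seconds (defaults 50 / 100 / 200 ms).
#' @param peak_amplitudes Three signed amplitudes (arbitrary units).
#' @param width_s Gaussian bump standard deviation in seconds.
#' @param span_s Kernel span in seconds; the lag axis runs from 0 to
#'   `span_s` inclusive.
#' @return An object of class `erp_kernel` with fields `lag_s`, `amplitude`
#'   and `rate`.
#' @export
make_triphasic_kernel <- function(rate,
                                  peak_latencies_s = c(0.05, 0.10, 0.20),
                                  peak_amplitudes = c(1, -2, 1),
                                  width_s = 0.015,
                                  span_s = 0.5) {
  stopifnot(rate > 0, length(peak_latencies_s) == 3,
            length(peak_amplitudes) == 3, width_s > 0, span_s > 0)
  if (is.unsorted(peak_latencies_s, strictly = TRUE)) {
    abort("peak latencies must be strictly increasing")
  }
  if (any(peak_latencies_s < 0) || any(peak_latencies_s > span_s) ||
      span_s > 0.5 + 1e-12) {
    abort("peak latencies must lie in [0, span_s] with span_s <= 0.5 s")
  }
  lag_s <- seq(0, span_s, by = 1 / rate)
  amp <- rep(0, length(lag_s))
  for (j in 1:3) {
    amp <- amp + peak_amplitudes[j] *
      exp(-((lag_s - peak_latencies_s[j])^2) / (2 * width_s^2))
  }
  if (any(peak_amplitudes != 0)) {
    taper_len <- min(0.02, peak_latencies_s[1] / 2,
                     (span_s - peak_latencies_s[3]) / 2)
    nt <- max(2L, round(taper_len * rate))
    if (nt < length(lag_s) / 2) {
      ramp <- 0.5 - 0.5 * cos(pi * (seq_len(nt) - 1) / (nt - 1))
      amp[seq_len(nt)] <- amp[seq_len(nt)] * ramp
      idx <- (length(amp) - nt + 1):length(amp)
      amp[idx] <- amp[idx] * rev(ramp)
    }
  }
  structure(list(lag_s = lag_s, amplitude = amp, rate = rate),
            class = "erp_kernel")
}

#' @export
print.erp_kernel <- function(x, ...) {
  cat(sprintf("<erp_kernel> span %.3f s @ %g Hz (%d lags)\n",
              max(x$lag_s), x$rate, length(x$lag_s)))
  invisible(x)
}

#' @export
length.erp_kernel <- function(x) length(x$amplitude)

#' @rdname make_triphasic_kernel
#' @param x An `erp_kernel`.
#' @param ... Unused.
#' @method tidy erp_kernel
#' @export
tidy.erp_kernel <- function(x, ...) {
  tibble::tibble(lag_s = x$lag_s, amplitude = x$amplitude)
}
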