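# Internal helpers shared across modules.

# Periodic-symmetric Hann window, normalized to unit sum when `normalize`.
hann_window <- function(n, normalize = FALSE) {
  stopifnot(n >= 1)
  w <- if (n == 1) 1 else 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  if (normalize) w <- w / sum(w)
  w
}

# Centered FFT convolution of x with kernel k, output same length as x.
# Zero padding at the edges (same convention as stats::filter(sides = 2)).
fft_conv_same <- function(x, k) {
  n <- length(x)
  m <- length(k)
  nf <- stats::nextn(n + m - 1L, 2L)
  y <- Re(fft(fft(c(x, rep(0, nf - n))) * fft(c(k, rep(0, nf - m))),
              inverse = TRUE)) / nf
  # full convolution index of x[i] aligned with kernel center
  offset <- floor((m - 1) / 2)
  y[(1 + offset):(n + offset)]
}

# Map times (s) to 1-based sample indices at `rate`, spec convention
# sample k (0-based) <-> time k / rate.
time_to_index <- function(t, rate) as.integer(round(t * rate)) + 1L

is_binary01 <- function(x) all(x %in% c(0, 1))

# Derive a vector of child seeds deterministically from one parent seed,
# keeping values within the 32-bit integer range.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
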