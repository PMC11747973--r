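#' Pink (1/f) noise
#'
#' Generates channels of 1/f noise by spectral shaping of Gaussian white
#' noise: the FFT of a white sequence is multiplied by `f^(-1/2)` (so power
#' goes as 1/f), the DC bin is zeroed, and each channel is normalized to
#' unit sample variance. Channels are independent and the output is a pure
#' function of the seed.
#'
#' @param n_samples Number of samples (>= 2).
#' @param n_channels Number of independent channels.
#' @param seed Integer seed.
#' @return A `n_samples x n_channels` numeric matrix.
#' @export
pink_noise <- function(n_samples, n_channels = 1, seed) {
  stopifnot(n_samples >= 2, n_channels >= 1)
  if (missing(seed)) abort("`seed` is required: pink noise is stochastic")
  g <- pink_shaping_gain(n_samples)
  withr::with_seed(as.integer(seed), {
    out <- matrix(0, n_samples, n_channels)
    for (ch in seq_len(n_channels)) {
      w <- rnorm(n_samples)
      x <- Re(fft(fft(w) * g, inverse = TRUE)) / n_samples
      out[, ch] <- x / sd(x)
    }
    out
  })
}

# Amplitude gain per FFT bin for 1/f power shaping (DC zeroed), in the
# Hermitian-symmetric layout matching stats::fft of a real sequence.
pink_shaping_gain <- function(n) {
  k <- seq_len(n) - 1L                    # 0 .. n-1
  f <- pmin(k, n - k)                     # folded bin frequency
  g <- numeric(n)
  nz <- f > 0
  g[nz] <- f[nz]^(-0.5)
  g
}

# Theoretical autocovariance (lag 0..n-1, unit marginal variance) of the
# shaped noise above; used to predict the standard deviation seen inside a
# short baseline window, which is well below the marginal sd for 1/f noise.
pink_autocovariance <- function(n) {
  g <- pink_shaping_gain(n)
  acv <- Re(fft(g^2, inverse = TRUE)) / n
  acv / acv[1]
}

# Expected sample variance (denominator w-1) within a window of w
# consecutive samples of a stationary process with autocorrelation rho.
expected_window_variance <- function(rho, w) {
  if (w < 2) return(0)
  d <- seq_len(w - 1)
  1 - (2 / (w * (w - 1))) * sum((w - d) * rho[d + 1])
}
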