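#' Build a lagged (time-delayed) design matrix
#'
#' Expands a stimulus feature matrix into the ridge design `S`: one column
#' per (feature, lag) pair holding `s_f(t - tau)`, zero-padded where the
#' shift runs outside the recording (zero padding at non-zero lags keeps
#' the model causal in the sense that no sample wraps around). Lags run
#' from `round(tmin_ms * rate / 1000)` to `round(tmax_ms * rate / 1000)`
#' samples inclusive; positive lags mean the stimulus precedes the
#' response. Columns are ordered feature-major with lags ascending within
#' each feature.
#'
#' @param features A [feature_set()] or numeric matrix.
#' @param tmin_ms,tmax_ms Lag window bounds in milliseconds (default
#'   `[-100, 500]`, which at 100 Hz gives 61 lags).
#' @param rate Sampling rate in Hz (taken from the feature set when
#'   omitted).
#' @return An object of class `lagged_design` with fields `matrix`, `lags`
#'   (sample lags), `tmin_ms`, `tmax_ms`, `rate`, `n_features`,
#'   `feature_names`.
#' @export
build_lagged_design <- function(features, tmin_ms = -100, tmax_ms = 500,
                                rate = NULL) {
  if (inherits(features, "feature_set")) {
    rate <- rate %||% features$rate
    fnames <- features$names
  } else {
    fnames <- colnames(features) %||%
      sprintf("f%02d", seq_len(ncol(as.matrix(features))))
  }
  if (is.null(rate)) abort("`rate` is required for a bare feature matrix")
  if (tmin_ms >= tmax_ms) abort("tmin_ms must be smaller than tmax_ms")
  s <- as_feature_matrix(features)
  if (ncol(s) == 0 || nrow(s) == 0) abort("empty feature matrix")
  if (any(!is.finite(s))) abort("features must be finite")
  lags <- seq.int(round(tmin_ms * rate / 1000), round(tmax_ms * rate / 1000))
  n <- nrow(s)
  nf <- ncol(s)
  out <- matrix(0, n, nf * length(lags))
  for (f in seq_len(nf)) {
    for (li in seq_along(lags)) {
      tau <- lags[li]
      col <- (f - 1L) * length(lags) + li
      if (tau >= 0) {
        if (tau < n) out[(tau + 1L):n, col] <- s[1:(n - tau), f]
      } else {
        a <- -tau
        if (a < n) out[1:(n - a), col] <- s[(a + 1L):n, f]
      }
    }
  }
  structure(list(matrix = out, lags = lags, tmin_ms = tmin_ms,
                 tmax_ms = tmax_ms, rate = rate, n_features = nf,
                 feature_names = fnames),
            class = "lagged_design")
}

#' @export
print.lagged_design <- function(x, ...) {
  cat(sprintf(
    "<lagged_design> %d samples, %d features x %d lags (%g..%g ms @ %g Hz)\n",
    nrow(x$matrix), x$n_features, length(x$lags), x$tmin_ms, x$tmax_ms,
    x$rate))
  invisible(x)
}

#' @export
dim.lagged_design <- function(x) dim(x$matrix)
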