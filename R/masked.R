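#' Explainable-sample mask for discrete-feature models
#'
#' A discrete (event-marker) model can only predict EEG inside the TRF lag
#' window around events; everywhere else its prediction is exactly zero and
#' carries no information. The mask marks sample `t` as explainable iff
#' some event onset `e` in a discrete column satisfies
#' `t \in [e + tmin, e + tmax]` (union over events and columns). A feature
#' set containing any continuous column predicts every sample, so its mask
#' is all-true.
#'
#' @param features A [feature_set()].
#' @param tmin_ms,tmax_ms The lag window of the TRF to be evaluated, in ms.
#' @return An object of class `explainable_mask`: list with `mask`
#'   (logical per sample), `proportion`, `source_features`, `tmin_ms`,
#'   `tmax_ms`.
#' @export
explainable_mask <- function(features, tmin_ms = -100, tmax_ms = 500) {
  stopifnot(inherits(features, "feature_set"))
  n_col <- ncol(features$data)
  if (n_col == 0) abort("feature set has no columns")
  n <- nrow(features$data)
  if (any(!features$discrete)) {
    mask <- rep(TRUE, n)
    src <- features$names[!features$discrete]
  } else {
    rate <- features$rate
    lag_lo <- round(tmin_ms * rate / 1000)
    lag_hi <- round(tmax_ms * rate / 1000)
    mask <- rep(FALSE, n)
    for (j in seq_len(n_col)) {
      for (e in which(features$data[, j] == 1)) {
        i0 <- max(1L, e + lag_lo)
        i1 <- min(n, e + lag_hi)
        if (i1 >= i0) mask[i0:i1] <- TRUE
      }
    }
    src <- features$names
  }
  structure(list(mask = mask, proportion = mean(mask),
                 source_features = src, tmin_ms = tmin_ms,
                 tmax_ms = tmax_ms),
            class = "explainable_mask")
}

#' @export
print.explainable_mask <- function(x, ...) {
  cat(sprintf("<explainable_mask> %.1f%% of %d samples, window [%g, %g] ms\n",
              100 * x$proportion, length(x$mask), x$tmin_ms, x$tmax_ms))
  invisible(x)
}

#' Export a mask as a start/end interval table
#'
#' @param x An [explainable_mask()].
#' @param rate Sampling rate in Hz used to convert samples to seconds.
#' @param ... Unused.
#' @return A tibble with `start_s`, `end_s` (half-open intervals).
#' @method tidy explainable_mask
#' @export
tidy.explainable_mask <- function(x, rate = 100, ...) {
  r <- rle(x$mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble::tibble(start_s = (starts[keep] - 1) / rate,
                 end_s = ends[keep] / rate)
}

#' Score a TRF only on explainable samples
#'
#' Computes per-channel prediction correlations restricted to mask-true
#' samples (all mask-true samples within the scored stretch are
#' concatenated before correlating) and reports the explainable proportion
#' alongside. With an all-true mask this reduces bit-exactly to plain
#' scoring.
#'
#' @param trf A fitted [fit_trf()] object.
#' @param features Features to predict from.
#' @param eeg The measured EEG ([eeg_recording()] or matrix).
#' @param mask An [explainable_mask()] or logical vector of length T.
#' @return List with `r` (per channel), `mean_r`, `proportion`.
#' @export
masked_scores <- function(trf, features, eeg, mask) {
  m <- if (inherits(mask, "explainable_mask")) mask$mask else
    as.logical(mask)
  y <- if (inherits(eeg, "eeg_recording")) eeg$data else as.matrix(eeg)
  if (length(m) != nrow(y)) abort("mask length must equal the sample count")
  pred <- predict(trf, features)
  if (sum(m) < 3) {
    warn("fewer than 3 explainable samples: scores undefined")
    r <- rep(NA_real_, ncol(y))
  } else {
    r <- pearson_by_channel(pred, y, m)
  }
  list(r = r, mean_r = mean(r, na.rm = TRUE), proportion = mean(m))
}
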