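#' Fit a ridge-regularized temporal response function
#'
#' Solves the regularized normal equations per channel,
#' `w = (S'S + lambda I)^-1 S' r`; at `lambda = 0` this reduces to the
#' ordinary least-squares normal equation. The penalty is a plain
#' `lambda I` over all lag columns with no intercept (the EEG is expected
#' to be z-scored).
#'
#' @param design A [build_lagged_design()] result, or a plain numeric
#'   matrix (treated as a single-lag design).
#' @param eeg An [eeg_recording()] or numeric matrix with matching rows.
#' @param lambda Ridge strength, `>= 0`.
#' @return An object of class `trf` with fields `weights` (a
#'   feature x lag x channel array), `lambda`, `tmin_ms`, `tmax_ms`,
#'   `rate`, `feature_names`, `channel_names` and `residual_rms` (training
#'   residual RMS per channel).
#' @export
fit_ridge <- function(design, eeg, lambda) {
  stopifnot(lambda >= 0)
  plain <- !inherits(design, "lagged_design")
  s <- if (plain) as.matrix(design) else design$matrix
  r <- if (inherits(eeg, "eeg_recording")) eeg$data else as.matrix(eeg)
  if (nrow(s) != nrow(r)) abort("design and EEG must have the same rows")
  g <- crossprod(s)
  cc <- crossprod(s, r)
  w <- ridge_solve(g, cc, lambda)
  resid <- r - s %*% w
  meta <- if (plain) {
    list(lags = 0L, tmin_ms = 0, tmax_ms = 0, rate = NA_real_,
         n_features = ncol(s),
         feature_names = colnames(s) %||% sprintf("f%02d", seq_len(ncol(s))))
  } else {
    design
  }
  nl <- length(meta$lags)
  nf <- meta$n_features
  nc <- ncol(r)
  weights <- aperm(array(w, dim = c(nl, nf, nc)), c(2, 1, 3))
  dimnames(weights) <- list(meta$feature_names, NULL,
                            colnames(r) %||% sprintf("ch%02d", seq_len(nc)))
  structure(list(weights = weights, lambda = lambda,
                 tmin_ms = meta$tmin_ms, tmax_ms = meta$tmax_ms,
                 rate = meta$rate, lags = meta$lags,
                 feature_names = meta$feature_names,
                 channel_names = dimnames(weights)[[3]],
                 residual_rms = sqrt(colMeans(resid^2))),
            class = "trf")
}

ridge_solve <- function(g, cc, lambda) {
  a <- g + diag(lambda, nrow(g))
  ch <- tryCatch(chol(a), error = function(e) NULL)
  if (is.null(ch)) {
    if (lambda == 0) {
      abort("S'S is singular at lambda = 0; use lambda > 0")
    }
    abort("regularized normal equations are numerically singular")
  }
  backsolve(ch, forwardsolve(t(ch), cc))
}

#' Fit a TRF directly from features and EEG
#'
#' Convenience wrapper around [build_lagged_design()] + [fit_ridge()].
#'
#' @inheritParams build_lagged_design
#' @inheritParams fit_ridge
#' @export
fit_trf <- function(features, eeg, lambda, tmin_ms = -100, tmax_ms = 500,
                    rate = NULL) {
  design <- build_lagged_design(features, tmin_ms, tmax_ms, rate)
  fit_ridge(design, eeg, lambda)
}

#' @export
print.trf <- function(x, ...) {
  d <- dim(x$weights)
  cat(sprintf(
    "<trf> %d feature(s) x %d lags x %d channel(s), lambda = %g, [%g, %g] ms\n",
    d[1], d[2], d[3], x$lambda, x$tmin_ms, x$tmax_ms))
  invisible(x)
}

# feature-major (lag fastest) weight matrix, P x C
trf_weight_matrix <- function(trf) {
  d <- dim(trf$weights)
  matrix(aperm(trf$weights, c(2, 1, 3)), d[1] * d[2], d[3])
}

#' Predict EEG from a fitted TRF
#'
#' Builds the lagged design of the new features with the TRF's own lag
#' window and multiplies by the weights; the response to a single impulse
#' feature is the TRF's lag profile placed at the impulse.
#'
#' @param object A [fit_trf()] / [fit_ridge()] result.
#' @param features A [feature_set()] or matrix with the same feature count
#'   (and rate, when known) as the TRF.
#' @param ... Unused.
#' @return A time x channel matrix of predicted EEG.
#' @export
predict.trf <- function(object, features, ...) {
  s <- as_feature_matrix(features)
  if (ncol(s) != dim(object$weights)[1]) {
    abort(sprintf("TRF expects %d feature column(s), got %d",
                  dim(object$weights)[1], ncol(s)))
  }
  if (inherits(features, "feature_set") && !is.na(object$rate) &&
      abs(features$rate - object$rate) > 1e-9) {
    abort("feature rate does not match the TRF rate")
  }
  if (identical(object$lags, 0L) || length(object$lags) == 1) {
    design <- s %*% trf_weight_matrix(object)
    return(design)
  }
  design <- build_lagged_design(s, object$tmin_ms, object$tmax_ms,
                                rate = object$rate)
  design$matrix %*% trf_weight_matrix(object)
}

#' Per-channel Pearson correlation between predicted and actual EEG
#'
#' The encoding-model performance metric: Pearson r per channel between
#' prediction and measurement, optionally restricted to a boolean sample
#' mask (see [explainable_mask()]). Channels with fewer than 3 unmasked
#' samples or zero variance yield `NA` and are excluded from averages
#' downstream.
#'
#' @param pred,actual Equal-shaped time x channel matrices (or
#'   `eeg_recording` for `actual`).
#' @param mask Optional logical vector, one entry per sample; `NULL` scores
#'   every sample.
#' @return Named numeric vector of per-channel correlations.
#' @export
pearson_by_channel <- function(pred, actual, mask = NULL) {
  a <- if (inherits(actual, "eeg_recording")) actual$data else
    as.matrix(actual)
  p <- as.matrix(pred)
  if (!all(dim(p) == dim(a))) abort("pred and actual shapes differ")
  if (!is.null(mask)) {
    stopifnot(length(mask) == nrow(a))
    p <- p[mask, , drop = FALSE]
    a <- a[mask, , drop = FALSE]
  }
  out <- rep(NA_real_, ncol(a))
  names(out) <- colnames(a)
  if (nrow(a) >= 3) {
    sp <- apply(p, 2, sd)
    sa <- apply(a, 2, sd)
    ok <- sp > 0 & sa > 0
    if (any(ok)) {
      out[ok] <- vapply(which(ok), function(j) cor(p[, j], a[, j]),
                        numeric(1))
    }
  }
  out
}
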