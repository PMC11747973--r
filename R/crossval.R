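#' Default ridge-strength search grid
#'
#' Nine log-spaced values from 1e-4 to 1e4 in multiplicative steps of 10.
#'
#' @return Numeric vector of candidate lambdas.
#' @export
default_lambda_grid <- function() 10^seq(-4, 4)

#' Split a recording into contiguous segments
#'
#' Partitions `[1, n_samples]` into `n_segments` contiguous ranges whose
#' lengths differ by at most one sample; in cross-validation each segment
#' serves as the held-out test set exactly once.
#'
#' @param n_samples Total number of samples.
#' @param n_segments Number of segments (>= 2).
#' @return A tibble with columns `segment`, `start`, `end` (inclusive,
#'   1-based).
#' @export
segment_split <- function(n_samples, n_segments) {
  stopifnot(n_segments >= 2, n_samples >= n_segments)
  bounds <- round(seq(0, n_samples, length.out = n_segments + 1))
  tibble::tibble(segment = seq_len(n_segments),
                 start = bounds[-length(bounds)] + 1L,
                 end = bounds[-1])
}

segment_rows <- function(split, segment) {
  seq.int(split$start[segment], split$end[segment])
}

#' Z-score EEG per channel within each segment
#'
#' Standardizes every channel to mean 0 and standard deviation 1 inside
#' each segment, so that prediction scores are comparable between segments.
#'
#' @param eeg An [eeg_recording()] or matrix.
#' @param split A [segment_split()] tibble.
#' @return Same type as `eeg`, standardized.
#' @export
zscore_by_segment <- function(eeg, split) {
  is_rec <- inherits(eeg, "eeg_recording")
  x <- if (is_rec) eeg$data else as.matrix(eeg)
  for (s in split$segment) {
    rows <- segment_rows(split, s)
    for (ch in seq_len(ncol(x))) {
      v <- x[rows, ch]
      sdv <- sd(v)
      if (sdv == 0) {
        abort(sprintf("channel %d is constant within segment %d", ch, s))
      }
      x[rows, ch] <- (v - mean(v)) / sdv
    }
  }
  if (is_rec) eeg_recording(x, eeg$rate, eeg$channel_names) else x
}

#' Segment a recording and z-score the neural data
#'
#' @inheritParams zscore_by_segment
#' @param features A [feature_set()] aligned with `eeg` (returned
#'   unchanged; provided so downstream code can keep the pair together).
#' @param n_segments Number of contiguous segments.
#' @return List with `split`, `eeg` (z-scored) and `features`.
#' @export
segment_and_zscore <- function(eeg, features = NULL, n_segments = 6) {
  n <- if (inherits(eeg, "eeg_recording")) nrow(eeg$data) else nrow(eeg)
  split <- segment_split(n, n_segments)
  list(split = split, eeg = zscore_by_segment(eeg, split),
       features = features)
}

# Per-segment Gram blocks of a lagged design: G_s = X_s' X_s, c_s = X_s' Y_s.
# Sums over any subset of segments give the training normal equations, so
# the lambda search reuses one pass over the data.
segment_grams <- function(x, y, split) {
  lapply(split$segment, function(s) {
    rows <- segment_rows(split, s)
    xs <- x[rows, , drop = FALSE]
    list(g = crossprod(xs), c = crossprod(xs, y[rows, , drop = FALSE]))
  })
}

sum_grams <- function(grams, segments) {
  g <- grams[[segments[1]]]$g
  cc <- grams[[segments[1]]]$c
  for (s in segments[-1]) {
    g <- g + grams[[s]]$g
    cc <- cc + grams[[s]]$c
  }
  list(g = g, c = cc)
}

mean_channel_r <- function(pred, actual, mask = NULL) {
  mean(pearson_by_channel(pred, actual, mask), na.rm = TRUE)
}

#' Select the ridge strength by segment-wise cross-validation
#'
#' For every fold (each segment is the validation set once, the rest
#' train), fits a TRF at every candidate lambda and scores the mean
#' channel correlation on the validation segment; the selected lambda
#' maximizes the mean score across folds, with ties broken toward the
#' smaller lambda. The search is exhaustive over the grid.
#'
#' @param features A [feature_set()] (or matrix; then give `rate`).
#' @param eeg An [eeg_recording()] or matrix, typically z-scored per
#'   segment.
#' @param split A [segment_split()] tibble.
#' @param lambda_grid Candidate lambdas (default [default_lambda_grid()]).
#' @param tmin_ms,tmax_ms Lag window in ms.
#' @param rate Sampling rate for bare matrices.
#' @return List with `lambda` (selected), `lambda_table` (per-lambda mean
#'   score) and `scores` (per fold x lambda).
#' @export
cv_lambda <- function(features, eeg, split,
                      lambda_grid = default_lambda_grid(),
                      tmin_ms = -100, tmax_ms = 500, rate = NULL) {
  if (length(lambda_grid) == 0) abort("lambda grid is empty")
  lambda_grid <- sort(lambda_grid)
  design <- build_lagged_design(features, tmin_ms, tmax_ms, rate)
  y <- if (inherits(eeg, "eeg_recording")) eeg$data else as.matrix(eeg)
  grams <- segment_grams(design$matrix, y, split)
  scores <- cv_lambda_scores(design$matrix, y, grams, split,
                             split$segment, lambda_grid)
  tab <- dplyr::summarise(scores,
                          mean_score = mean(.data$score, na.rm = TRUE),
                          .by = "lambda")
  list(lambda = pick_lambda(tab), lambda_table = tab, scores = scores)
}

# Smallest lambda among the score maximizers; errors when no fold produced
# a defined score at any lambda.
pick_lambda <- function(tab) {
  if (all(!is.finite(tab$mean_score))) {
    abort("all cross-validation scores are undefined")
  }
  tab$lambda[which.max(tab$mean_score)]
}

# Inner machinery shared by cv_lambda and trf_crossval: score every lambda
# with each of `val_segments` held out, training on the remaining
# `pool_segments`.
cv_lambda_scores <- function(x, y, grams, split, pool_segments,
                             lambda_grid, exclude = integer()) {
  rows_list <- lapply(pool_segments, function(v) segment_rows(split, v))
  out <- vector("list", length(pool_segments))
  for (i in seq_along(pool_segments)) {
    v <- pool_segments[i]
    train <- setdiff(pool_segments, c(v, exclude))
    nr <- sum_grams(grams, train)
    xv <- x[rows_list[[i]], , drop = FALSE]
    yv <- y[rows_list[[i]], , drop = FALSE]
    sc <- vapply(lambda_grid, function(l) {
      w <- ridge_solve(nr$g, nr$c, l)
      mean_channel_r(xv %*% w, yv)
    }, numeric(1))
    out[[i]] <- tibble::tibble(fold = v, lambda = lambda_grid, score = sc)
  }
  dplyr::bind_rows(out)
}

#' Cross-validated TRF evaluation protocol
#'
#' The full encoding-model protocol: the EEG is split into contiguous
#' segments and z-scored per segment; each segment serves as held-out test
#' set once; within every fold, the ridge strength is selected by an inner
#' cross-validation over the training segments only, the TRF is refit on
#' all training segments at the selected lambda, and the held-out segment
#' is scored by the mean channel correlation (optionally also restricted to
#' an explainable-sample mask).
#'
#' @inheritParams cv_lambda
#' @param n_segments Number of contiguous segments (6 by default; 10 for
#'   nested feature-set comparisons).
#' @param mask Optional logical vector (see [explainable_mask()]); adds a
#'   `score_masked` column.
#' @param zscore Standardize the EEG per segment first (default `TRUE`).
#' @return List of class `trf_crossval`: `scores` (tibble with `fold`,
#'   `lambda`, `score`, optionally `score_masked`), `split`, and `trf`
#'   (fitted on all data at the modal selected lambda).
#' @export
trf_crossval <- function(features, eeg, n_segments = 6,
                         lambda_grid = default_lambda_grid(),
                         tmin_ms = -100, tmax_ms = 500, mask = NULL,
                         zscore = TRUE, rate = NULL) {
  lambda_grid <- sort(lambda_grid)
  y <- if (inherits(eeg, "eeg_recording")) eeg$data else as.matrix(eeg)
  split <- segment_split(nrow(y), n_segments)
  if (zscore) y <- zscore_by_segment(y, split)
  design <- build_lagged_design(features, tmin_ms, tmax_ms, rate)
  if (nrow(design$matrix) != nrow(y)) {
    abort("features and EEG must have the same number of samples")
  }
  x <- design$matrix
  grams <- segment_grams(x, y, split)
  res <- vector("list", n_segments)
  for (o in split$segment) {
    train <- setdiff(split$segment, o)
    lam <- if (length(lambda_grid) == 1) lambda_grid else {
      cv_lambda_scores(x, y, grams, split, train, lambda_grid,
                       exclude = o) |>
        dplyr::summarise(mean_score = mean(.data$score, na.rm = TRUE),
                         .by = "lambda") |>
        pick_lambda()
    }
    nr <- sum_grams(grams, train)
    w <- ridge_solve(nr$g, nr$c, lam)
    rows <- segment_rows(split, o)
    pred <- x[rows, , drop = FALSE] %*% w
    row <- tibble::tibble(
      fold = o, lambda = lam,
      score = mean_channel_r(pred, y[rows, , drop = FALSE])
    )
    if (!is.null(mask)) {
      row$score_masked <- mean_channel_r(pred, y[rows, , drop = FALSE],
                                         mask[rows])
    }
    res[[o]] <- row
  }
  scores <- dplyr::bind_rows(res)
  lam_final <- modal_lambda(scores$lambda)
  full <- sum_grams(grams, split$segment)
  w_full <- ridge_solve(full$g, full$c, lam_final)
  trf <- fit_from_weights(design, w_full, lam_final, y, x)
  structure(list(scores = scores, split = split, trf = trf),
            class = "trf_crossval")
}

modal_lambda <- function(lams) {
  tab <- table(lams)
  as.numeric(names(tab)[which.max(tab)])   # ties break toward smaller lambda
}

fit_from_weights <- function(design, w, lambda, y, x) {
  resid <- y - x %*% w
  nl <- length(design$lags)
  nf <- design$n_features
  nc <- ncol(y)
  weights <- aperm(array(w, dim = c(nl, nf, nc)), c(2, 1, 3))
  dimnames(weights) <- list(design$feature_names, NULL,
                            colnames(y) %||% sprintf("ch%02d", seq_len(nc)))
  structure(list(weights = weights, lambda = lambda,
                 tmin_ms = design$tmin_ms, tmax_ms = design$tmax_ms,
                 rate = design$rate, lags = design$lags,
                 feature_names = design$feature_names,
                 channel_names = dimnames(weights)[[3]],
                 residual_rms = sqrt(colMeans(resid^2))),
            class = "trf")
}
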