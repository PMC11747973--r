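#' Cross-prediction between two single-column feature models
#'
#' Trains a TRF for feature A and one for feature B on the same training
#' segments and scores four combinations on every held-out segment: the two
#' within-model scores (A weights on A features, B on B) and the two
#' cross-model scores (A weights applied to B features and vice versa), all
#' channel-averaged. High correlation between within and cross scores
#' indicates that the two models' weights generalize to each other's
#' feature information. Only single-column features are admitted so that
#' the weight dimensions are consistent between the paired models.
#'
#' @param feat_a,feat_b One-column [feature_set()] objects of equal length.
#' @param eeg An [eeg_recording()] or matrix.
#' @param shift_correction Apply the latency-shift correction: estimate the
#'   lag offset between the two TRFs via [estimate_latency_shift()] and
#'   shift the predicting feature accordingly before cross-predicting.
#' @param max_shift_ms Search window for the shift estimate.
#' @param cor_method Correlation between within and cross score vectors;
#'   `"spearman"` (default) or `"pearson"`.
#' @inheritParams trf_crossval
#' @return An object of class `cross_prediction`: `scores` (tibble with
#'   `fold`, `within_A`, `within_B`, `cross_AB`, `cross_BA`), `rho_on_A` /
#'   `rho_on_B` (within-vs-cross score correlations on each feature's
#'   information), `shift_samples`.
#' @export
cross_predict_pair <- function(feat_a, feat_b, eeg, n_segments = 6,
                               lambda_grid = default_lambda_grid(),
                               tmin_ms = -100, tmax_ms = 500,
                               shift_correction = FALSE, max_shift_ms = 150,
                               cor_method = c("spearman", "pearson")) {
  cor_method <- match.arg(cor_method)
  for (f in list(feat_a, feat_b)) {
    if (ncol(as_feature_matrix(f)) != 1) {
      abort(paste0("cross-prediction requires single-column features ",
                   "(feature dimensions must be consistent)"))
    }
  }
  if (nrow(as_feature_matrix(feat_a)) != nrow(as_feature_matrix(feat_b))) {
    abort("features must have equal length")
  }
  lambda_grid <- sort(lambda_grid)
  y <- if (inherits(eeg, "eeg_recording")) eeg$data else as.matrix(eeg)
  split <- segment_split(nrow(y), n_segments)
  y <- zscore_by_segment(y, split)
  rate <- feat_a$rate
  da <- build_lagged_design(feat_a, tmin_ms, tmax_ms)
  db <- build_lagged_design(feat_b, tmin_ms, tmax_ms)
  ga <- segment_grams(da$matrix, y, split)
  gb <- segment_grams(db$matrix, y, split)

  shift <- 0L
  if (shift_correction) {
    cva <- trf_crossval(feat_a, eeg, n_segments = n_segments,
                        lambda_grid = lambda_grid, tmin_ms = tmin_ms,
                        tmax_ms = tmax_ms)
    cvb <- trf_crossval(feat_b, eeg, n_segments = n_segments,
                        lambda_grid = lambda_grid, tmin_ms = tmin_ms,
                        tmax_ms = tmax_ms)
    shift <- estimate_latency_shift(cva$trf, cvb$trf, max_shift_ms)
  }
  # TRF_B peaks `shift` samples after TRF_A: when A's weights predict from
  # B's features the events must be delayed by `shift` (and advanced for
  # the converse direction) so that the expected response latencies line up.
  db_shifted <- if (shift == 0) db else
    build_lagged_design(shift_feature(feat_b, shift), tmin_ms, tmax_ms)
  da_shifted <- if (shift == 0) da else
    build_lagged_design(shift_feature(feat_a, -shift), tmin_ms, tmax_ms)

  res <- vector("list", n_segments)
  for (o in split$segment) {
    train <- setdiff(split$segment, o)
    rows <- segment_rows(split, o)
    yv <- y[rows, , drop = FALSE]
    wa <- fit_fold(da$matrix, y, ga, split, train, o, lambda_grid)
    wb <- fit_fold(db$matrix, y, gb, split, train, o, lambda_grid)
    res[[o]] <- tibble::tibble(
      fold = o,
      within_A = mean_channel_r(da$matrix[rows, , drop = FALSE] %*% wa, yv),
      within_B = mean_channel_r(db$matrix[rows, , drop = FALSE] %*% wb, yv),
      cross_AB = mean_channel_r(
        db_shifted$matrix[rows, , drop = FALSE] %*% wa, yv),
      cross_BA = mean_channel_r(
        da_shifted$matrix[rows, , drop = FALSE] %*% wb, yv)
    )
  }
  scores <- dplyr::bind_rows(res)
  structure(list(
    scores = scores,
    rho_on_A = score_correlation(scores$within_A, scores$cross_BA,
                                 method = cor_method),
    rho_on_B = score_correlation(scores$within_B, scores$cross_AB,
                                 method = cor_method),
    shift_samples = shift,
    cor_method = cor_method
  ), class = "cross_prediction")
}

# Inner-CV lambda selection + refit for one outer fold.
fit_fold <- function(x, y, grams, split, train, out_seg, lambda_grid) {
  lam <- if (length(lambda_grid) == 1) lambda_grid else {
    cv_lambda_scores(x, y, grams, split, train, lambda_grid,
                     exclude = out_seg) |>
      dplyr::summarise(mean_score = mean(.data$score, na.rm = TRUE),
                       .by = "lambda") |>
      pick_lambda()
  }
  nr <- sum_grams(grams, train)
  ridge_solve(nr$g, nr$c, lam)
}

shift_feature <- function(fs, shift) {
  v <- fs$data[, 1]
  n <- length(v)
  out <- rep(0, n)
  if (shift >= 0) {
    if (shift < n) out[(shift + 1):n] <- v[1:(n - shift)]
  } else {
    a <- -shift
    if (a < n) out[1:(n - a)] <- v[(a + 1):n]
  }
  feature_set(out, fs$rate, names = fs$names, discrete = fs$discrete)
}

#' @export
print.cross_prediction <- function(x, ...) {
  cat(sprintf(
    "<cross_prediction> %d folds, rho(on A) = %.3f, rho(on B) = %.3f, shift = %d\n",
    nrow(x$scores), x$rho_on_A, x$rho_on_B, x$shift_samples))
  invisible(x)
}

#' @rdname cross_predict_pair
#' @param x A `cross_prediction`.
#' @param ... Unused.
#' @method tidy cross_prediction
#' @export
tidy.cross_prediction <- function(x, ...) {
  tidyr::pivot_longer(x$scores, -"fold", names_to = "score_type",
                      values_to = "mean_channel_r")
}

#' @rdname cross_predict_pair
#' @method glance cross_prediction
#' @export
glance.cross_prediction <- function(x, ...) {
  tibble::tibble(rho_on_A = x$rho_on_A, rho_on_B = x$rho_on_B,
                 shift_samples = x$shift_samples,
                 cor_method = x$cor_method)
}

#' Correlation between matched within- and cross-prediction scores
#'
#' Rank (Spearman) correlation by default, across pooled fold (and unit)
#' scores; rank-based so that any strictly monotone transform of the scores
#' leaves the result unchanged.
#'
#' @param within,cross Equal-length paired score vectors (n >= 5 unless
#'   `min_n` is lowered).
#' @param method `"spearman"` or `"pearson"`.
#' @param min_n Minimal number of pairs.
#' @return Correlation coefficient (NA with a warning for constant input).
#' @export
score_correlation <- function(within, cross,
                              method = c("spearman", "pearson"),
                              min_n = 5) {
  method <- match.arg(method)
  stopifnot(length(within) == length(cross))
  if (length(within) < min_n) abort("too few paired scores")
  if (sd(within) == 0 || sd(cross) == 0) {
    warn("constant score vector: correlation undefined")
    return(NA_real_)
  }
  cor(within, cross, method = method)
}

#' Estimate the latency shift between two TRFs
#'
#' Cross-correlates the channel-RMS lag profiles of the two TRFs and
#' returns the integer sample shift (within `+/- max_shift_ms`) maximizing
#' their alignment; positive values mean the second TRF peaks later.
#' Feature pairs with similar weight trajectories but offset peaks score
#' poorly in cross-prediction unless this shift is corrected.
#'
#' @param trf_a,trf_b Fitted [fit_trf()] objects sharing a lag grid.
#' @param max_shift_ms Search half-window in milliseconds.
#' @return Integer sample shift (warns when the optimum sits on the search
#'   boundary).
#' @export
estimate_latency_shift <- function(trf_a, trf_b, max_shift_ms = 150) {
  if (!identical(trf_a$lags, trf_b$lags)) {
    abort("TRFs must share the same lag grid")
  }
  pa <- lag_profile_rms(trf_a)
  pb <- lag_profile_rms(trf_b)
  rate <- trf_a$rate
  max_shift <- max(1L, round(max_shift_ms * rate / 1000))
  shifts <- -max_shift:max_shift
  score <- vapply(shifts, function(s) {
    ia <- seq_along(pa)
    ib <- ia + s
    ok <- ib >= 1 & ib <= length(pb)
    if (sum(ok) < 3) return(-Inf)
    sum(pa[ia[ok]] * pb[ib[ok]])
  }, numeric(1))
  best <- shifts[which.max(score)]
  if (abs(best) == max_shift) {
    warn("optimal shift at the search boundary; widen max_shift_ms")
  }
  as.integer(best)
}

# RMS over features and channels, one value per lag.
lag_profile_rms <- function(trf) {
  apply(trf$weights, 2, function(m) sqrt(mean(m^2)))
}
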