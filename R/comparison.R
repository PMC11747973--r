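#' Nested feature-set comparison
#'
#' Runs the full cross-validated TRF protocol for several feature models on
#' the same recording, with identical segment boundaries and z-scoring
#' across models so that fold-wise scores are paired: the basis of the
#' acoustic -> +sound-identity -> +condition-split model ladder.
#'
#' @param models Named list of [feature_set()] objects (one per model).
#' @param eeg An [eeg_recording()] (or matrix plus `rate`).
#' @param n_segments Number of segments (10 by default for nested
#'   comparisons).
#' @param unit_id Identifier for the participant / replicate this recording
#'   belongs to, recorded in the output.
#' @param condition Optional condition label, recorded in the output.
#' @inheritParams trf_crossval
#' @return A `score_table` tibble with columns `model_id`, `unit_id`,
#'   `condition`, `fold`, `lambda`, `mean_channel_r`.
#' @export
nested_comparison <- function(models, eeg, n_segments = 10,
                              lambda_grid = default_lambda_grid(),
                              tmin_ms = -100, tmax_ms = 500,
                              unit_id = 1L, condition = NA_character_,
                              rate = NULL) {
  stopifnot(length(models) >= 1)
  if (is.null(names(models)) || any(names(models) == "")) {
    abort("`models` must be a fully named list of feature sets")
  }
  for (nm in names(models)) {
    if (ncol(as_feature_matrix(models[[nm]])) == 0) {
      abort(sprintf("model '%s' has zero features", nm))
    }
  }
  rows <- purrr::imap(models, function(fs, nm) {
    cvr <- trf_crossval(fs, eeg, n_segments = n_segments,
                        lambda_grid = lambda_grid, tmin_ms = tmin_ms,
                        tmax_ms = tmax_ms, rate = rate)
    dplyr::mutate(cvr$scores, model_id = nm, unit_id = unit_id,
                  condition = condition, .before = 1)
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::rename(mean_channel_r = "score")
  class(out) <- c("score_table", class(out))
  out
}

#' Wilcoxon signed-rank test for paired score distributions
#'
#' Two-sided paired signed-rank test on the smaller-rank-sum convention:
#' zero differences are dropped, ties receive average ranks, `W` is the
#' smaller of the positive- and negative-rank sums, and `Z` is the
#' tie-corrected normal deviate. The p-value is computed by exact
#' enumeration of all sign assignments for fewer than 10 informative pairs
#' and from the normal approximation otherwise.
#'
#' @param x,y Paired numeric vectors of equal length (>= 5 pairs).
#' @return A one-row tibble with `W`, `Z`, `p`, `n_effective`, `method`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 5) abort("need at least 5 pairs")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warn("all paired differences are zero; p = 1")
    return(tibble::tibble(W = 0, Z = 0, p = 1, n_effective = 0L,
                          method = "degenerate"))
  }
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  w <- min(w_pos, w_neg)
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- if (sigma2 > 0) (w_pos - mu) / sqrt(sigma2) else 0
  if (n < 10) {
    p <- exact_signed_rank_p(r, w)
    method <- "exact enumeration"
  } else {
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation"
  }
  tibble::tibble(W = w, Z = z, p = p, n_effective = n, method = method)
}

# P(min(rank-sum) <= w_obs) over all 2^n equiprobable sign assignments.
exact_signed_rank_p <- function(ranks, w_obs) {
  n <- length(ranks)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_pos_all <- as.numeric(signs %*% ranks)
  tot <- sum(ranks)
  w_min <- pmin(w_pos_all, tot - w_pos_all)
  mean(w_min <= w_obs)
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up FDR control at level `q`; adjusted p-values come from
#' [stats::p.adjust()] and are monotone by construction.
#'
#' @param p_values Numeric p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return A tibble with `p`, `p_adjusted`, `rejected`.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  adj <- stats::p.adjust(p_values, method = "BH")
  tibble::tibble(p = p_values, p_adjusted = adj, rejected = adj <= q)
}

#' Shuffle onset positions while preserving inter-onset intervals
#'
#' Permutes the multiset of inter-onset intervals and redraws the start
#' offset uniformly over the feasible slack, so the shuffled train has
#' exactly the original interval multiset and onset count but random
#' temporal alignment -- the construction behind the prediction noise
#' floor.
#'
#' @param onset_vector Binary 0/1 marker vector (>= 2 onsets).
#' @param seed Integer seed.
#' @return A shuffled binary vector of the same length and onset count.
#' @export
shuffle_preserving_ioi <- function(onset_vector, seed) {
  if (missing(seed)) abort("`seed` is required: the shuffle is stochastic")
  if (!is_binary01(onset_vector)) abort("onset vector must be binary 0/1")
  idx <- which(onset_vector == 1)
  if (length(idx) < 2) abort("need at least 2 onsets to shuffle")
  gaps <- diff(idx)
  n <- length(onset_vector)
  span <- sum(gaps)
  slack <- n - 1L - span
  withr::with_seed(as.integer(seed), {
    new_gaps <- gaps[sample.int(length(gaps))]
    start <- 1L + sample.int(slack + 1L, 1) - 1L
    new_idx <- start + cumsum(c(0L, new_gaps))
    out <- rep(0, n)
    out[new_idx] <- 1
    out
  })
}

#' Onset-shuffle prediction noise floor
#'
#' Repeats the full cross-validated TRF protocol on interval-preserving
#' shuffles of the onset vector; the 2.5 and 97.5 percentiles of the null
#' mean scores form the 95% noise-floor confidence interval against which
#' true-onset scores are judged.
#'
#' @param onsets A one-column discrete [feature_set()] or binary vector.
#' @param eeg An [eeg_recording()] or matrix.
#' @param n_perm Number of permutations (100 by default).
#' @param seed Integer seed.
#' @inheritParams trf_crossval
#' @return An object of class `noise_floor`: list with `null_scores`,
#'   `ci_low`, `ci_high`, `n_perm`.
#' @export
onset_noise_floor <- function(onsets, eeg, n_perm = 100, seed,
                              n_segments = 6,
                              lambda_grid = default_lambda_grid(),
                              tmin_ms = -100, tmax_ms = 500, rate = NULL) {
  stopifnot(n_perm >= 2)
  if (missing(seed)) abort("`seed` is required")
  if (inherits(onsets, "feature_set")) {
    rate <- onsets$rate
    v <- as.numeric(onsets$data[, 1])
  } else {
    v <- as.numeric(onsets)
  }
  seeds <- derive_seeds(seed, n_perm)
  null_scores <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    shuffled <- shuffle_preserving_ioi(v, seed = seeds[i])
    fs <- feature_set(shuffled, rate %||%
                        (if (inherits(eeg, "eeg_recording")) eeg$rate else
                          abort("`rate` is required")),
                      names = "onsets_shuffled", discrete = TRUE)
    cvr <- tryCatch(
      trf_crossval(fs, eeg, n_segments = n_segments,
                   lambda_grid = lambda_grid, tmin_ms = tmin_ms,
                   tmax_ms = tmax_ms),
      error = function(e) {
        abort(sprintf("fit failed at permutation %d: %s", i,
                      conditionMessage(e)))
      })
    # folds whose shuffled train has no onsets in the test segment give an
    # undefined (NA) fold score; they are excluded from the null mean
    null_scores[i] <- mean(cvr$scores$score, na.rm = TRUE)
  }
  if (any(!is.finite(null_scores))) {
    warn(sprintf("%d permutation(s) had no defined fold score",
                 sum(!is.finite(null_scores))))
  }
  ci <- unname(quantile(null_scores[is.finite(null_scores)],
                        c(0.025, 0.975)))
  structure(list(null_scores = null_scores, ci_low = ci[1], ci_high = ci[2],
                 n_perm = n_perm),
            class = "noise_floor")
}

#' @export
print.noise_floor <- function(x, ...) {
  cat(sprintf("<noise_floor> %d permutations, 95%% CI [%.4f, %.4f]\n",
              x$n_perm, x$ci_low, x$ci_high))
  invisible(x)
}

#' Cluster-based permutation test on TRF weights over time
#'
#' Compares two paired sets of channel-aggregated TRF lag profiles
#' (units x lags). A paired t statistic is computed per lag; contiguous
#' lags exceeding the cluster-forming threshold (two-sided at
#' `alpha_cluster`) form clusters scored by their summed t. The null
#' distribution of the maximum absolute cluster sum is built by randomly
#' flipping the sign of each unit's difference; cluster p-values are the
#' proportion of null maxima at least as large as the observed cluster
#' score. Clustering runs over the time dimension only.
#'
#' @param weights_a,weights_b Numeric matrices, units x lags (>= 6 units).
#' @param n_perm Number of permutations (default 1000; fewer than 100
#'   triggers a coarse-resolution warning).
#' @param alpha_cluster Cluster-forming alpha (two-sided).
#' @param seed Integer seed.
#' @return A tibble with one row per cluster: `cluster`, `lag_start`,
#'   `lag_end` (1-based lag indices), `sum_t`, `p`.
#' @export
cluster_permutation_time <- function(weights_a, weights_b, n_perm = 1000,
                                     alpha_cluster = 0.05, seed = 1) {
  a <- as.matrix(weights_a)
  b <- as.matrix(weights_b)
  if (!all(dim(a) == dim(b))) abort("weight matrices must match in shape")
  if (nrow(a) < 6) abort("need at least 6 units for the permutation test")
  if (n_perm < 100) warn("n_perm < 100: cluster p-values are coarse")
  d <- a - b
  thr <- qt(1 - alpha_cluster / 2, nrow(d) - 1)
  obs <- time_clusters(paired_t(d), thr)
  if (nrow(obs) == 0) {
    return(tibble::tibble(cluster = integer(), lag_start = integer(),
                          lag_end = integer(), sum_t = numeric(),
                          p = numeric()))
  }
  null_max <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(i) {
      flips <- sample(c(-1, 1), nrow(d), replace = TRUE)
      cl <- time_clusters(paired_t(d * flips), thr)
      if (nrow(cl) == 0) 0 else max(abs(cl$sum_t))
    }, numeric(1))
  })
  obs$p <- vapply(obs$sum_t,
                  function(s) mean(null_max >= abs(s)), numeric(1))
  obs$cluster <- seq_len(nrow(obs))
  obs[, c("cluster", "lag_start", "lag_end", "sum_t", "p")]
}

paired_t <- function(d) {
  m <- colMeans(d)
  s <- apply(d, 2, sd) / sqrt(nrow(d))
  ifelse(s > 0, m / s, 0)
}

# Runs of same-sign supra-threshold lags.
time_clusters <- function(tvals, thr) {
  code <- ifelse(tvals > thr, 1L, ifelse(tvals < -thr, -1L, 0L))
  r <- rle(code)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0
  tibble::tibble(
    lag_start = starts[keep],
    lag_end = ends[keep],
    sum_t = vapply(which(keep),
                   function(i) sum(tvals[starts[i]:ends[i]]), numeric(1))
  )
}
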