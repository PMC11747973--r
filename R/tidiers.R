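#' Tidy a fitted TRF into a long tibble
#'
#' @param x A [fit_trf()] result.
#' @param ... Unused.
#' @return A tibble with `feature`, `lag_index`, `lag_ms`, `channel`,
#'   `weight`.
#' @method tidy trf
#' @export
tidy.trf <- function(x, ...) {
  d <- dim(x$weights)
  lag_ms <- if (!is.na(x$rate)) x$lags / x$rate * 1000 else x$lags
  tibble::tibble(
    feature = rep(x$feature_names, times = d[2] * d[3]),
    lag_index = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    lag_ms = rep(rep(lag_ms, each = d[1]), times = d[3]),
    channel = rep(x$channel_names, each = d[1] * d[2]),
    weight = as.vector(x$weights)
  )
}

#' @rdname tidy.trf
#' @method glance trf
#' @export
glance.trf <- function(x, ...) {
  d <- dim(x$weights)
  tibble::tibble(lambda = x$lambda, tmin_ms = x$tmin_ms,
                 tmax_ms = x$tmax_ms, rate = x$rate, n_features = d[1],
                 n_lags = d[2], n_channels = d[3],
                 mean_residual_rms = mean(x$residual_rms))
}

#' @method tidy trf_crossval
#' @export
tidy.trf_crossval <- function(x, ...) x$scores

#' @method glance trf_crossval
#' @export
glance.trf_crossval <- function(x, ...) {
  tibble::tibble(mean_score = mean(x$scores$score),
                 sd_score = sd(x$scores$score),
                 n_folds = nrow(x$scores),
                 lambda = x$trf$lambda)
}

#' @method tidy noise_floor
#' @export
tidy.noise_floor <- function(x, ...) {
  tibble::tibble(permutation = seq_along(x$null_scores),
                 score = x$null_scores)
}

#' @method glance noise_floor
#' @export
glance.noise_floor <- function(x, ...) {
  tibble::tibble(ci_low = x$ci_low, ci_high = x$ci_high, n_perm = x$n_perm,
                 null_mean = mean(x$null_scores))
}

#' Plot TRF lag profiles
#'
#' One line per channel, faceted by feature.
#'
#' @param object A [fit_trf()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trf
#' @export
autoplot.trf <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$lag_ms, y = .data$weight,
                                 group = .data$channel)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::facet_wrap(~ .data$feature, scales = "free_y") +
    ggplot2::labs(x = "lag (ms)", y = "TRF weight (a.u.)")
}

#' Plot an SNR sweep curve
#'
#' Whole-segment and explainable-only prediction accuracy against SNR.
#'
#' @param object An [run_snr_sweep()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot snr_curve
#' @export
autoplot.snr_curve <- function(object, ...) {
  tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("r_whole", "r_masked"), names_to = "scoring",
                        values_to = "r") |>
    dplyr::mutate(scoring = dplyr::recode(.data$scoring,
                                          r_whole = "whole segment",
                                          r_masked = "explainable only")) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$snr_db, y = .data$r,
                                 colour = .data$scoring)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "SNR (dB)", y = "mean prediction r",
                  colour = NULL)
}

#' Plot a variance partition
#'
#' Bar chart of unique and shared explained-variance terms.
#'
#' @param object A [partition_two()] / [partition_three()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot var_partition
#' @export
autoplot.var_partition <- function(object, ...) {
  tidy(object) |>
    dplyr::filter(grepl("^(unique|shared)_", .data$term)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$term, y = .data$r2)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = expression(R^2))
}

#' Plot a prediction noise floor
#'
#' Histogram of null scores with the 95% CI marked.
#'
#' @param object An [onset_noise_floor()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot noise_floor
#' @export
autoplot.noise_floor <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::geom_vline(xintercept = c(object$ci_low, object$ci_high),
                        linetype = 2) +
    ggplot2::labs(x = "null mean prediction r", y = "count")
}
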