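# Two-category recording whose alarm events carry a different (optionally
# condition-dependent) kernel than the rest; ground truth for the nested
# model ladder.
two_kernel_sim <- function(duration_s = 120, n_events = 80, snr_db = 5,
                           n_channels = 2, seed = 1,
                           alarm_gain = c(narrow = 1, wide = 1)) {
  rate <- 100
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, 2))
  events <- generate_event_train(duration_s, n_events, min_gap_s = 0.6,
                                 categories = c("generic", "alarm"),
                                 condition_split = c(narrow = 0.5,
                                                     wide = 0.5),
                                 seed = seeds[1])
  k_gen <- make_triphasic_kernel(rate)
  k_alarm <- make_triphasic_kernel(rate, c(0.08, 0.16, 0.30), c(2, -3, 2))
  n <- round(duration_s * rate)
  clean <- trfscape:::event_kernel_signal(
    events[events$category == "generic", ], k_gen, n, rate)
  for (cond in c("narrow", "wide")) {
    sel <- events[events$category == "alarm" & events$condition == cond, ]
    clean <- clean + alarm_gain[[cond]] *
      trfscape:::event_kernel_signal(sel, k_alarm, n, rate)
  }
  cal <- calibrate_noise_sd(k_gen, snr_db, n, rate)
  noise <- cal$sigma * pink_noise(n, n_channels, seed = seeds[2])
  eeg <- eeg_recording(matrix(clean, n, n_channels) + noise, rate)
  onsets <- events_to_markers(events, n, rate,
                              categories = c("generic", "alarm"))
  all_onsets <- feature_set(matrix(pmin(1, rowSums(onsets$data))), rate,
                            names = "onsets", discrete = TRUE)
  alarm <- events_to_markers(events, n, rate, categories = "alarm")
  alarm_cp <- events_to_markers(events, n, rate, categories = "alarm",
                                condition_split = TRUE)
  list(events = events, eeg = eeg, all_onsets = all_onsets, alarm = alarm,
       alarm_cp = alarm_cp)
}

grid3 <- c(0.01, 1, 100)

test_that("a model scores near-perfectly on its own noiseless data", {
  sim <- quick_sim(120, 80, snr_db = Inf, n_channels = 2, seed = 31)
  st <- nested_comparison(list(AC = sim$onsets), sim$eeg, n_segments = 6,
                          lambda_grid = grid3)
  expect_s3_class(st, "score_table")
  expect_equal(nrow(st), 6)
  expect_true(all(st$mean_channel_r > 0.99))
})

test_that("adding true sound-identity markers never hurts, on average", {
  diffs <- vapply(1:10, function(i) {
    sim <- two_kernel_sim(seed = 100 + i)
    st <- nested_comparison(
      list(base = sim$all_onsets,
           si = combine_features(sim$all_onsets, sim$alarm)),
      sim$eeg, n_segments = 6, lambda_grid = grid3)
    means <- tapply(st$mean_channel_r, st$model_id, mean)
    means[["si"]] - means[["base"]]
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gte(sum(diffs > 0), 8)
})

test_that("condition splits give no gain when both conditions share a kernel", {
  diffs <- vapply(1:8, function(i) {
    sim <- two_kernel_sim(seed = 200 + i)   # identical kernels per condition
    st <- nested_comparison(
      list(si = combine_features(sim$all_onsets, sim$alarm),
           cp = combine_features(sim$all_onsets, sim$alarm_cp)),
      sim$eeg, n_segments = 6, lambda_grid = grid3)
    means <- tapply(st$mean_channel_r, st$model_id, mean)
    means[["cp"]] - means[["si"]]
  }, numeric(1))
  expect_lt(mean(diffs), 0.005)
})

test_that("models in a comparison share fold boundaries (paired scores)", {
  sim <- two_kernel_sim(seed = 300)
  st <- nested_comparison(list(a = sim$all_onsets, b = sim$alarm),
                          sim$eeg, n_segments = 5, lambda_grid = 1)
  expect_equal(unname(table(st$model_id)), c(5L, 5L), ignore_attr = TRUE)
  expect_equal(st$fold[st$model_id == "a"], st$fold[st$model_id == "b"])
  expect_error(nested_comparison(list(sim$all_onsets), sim$eeg), "named")
})

test_that("the signed-rank test matches exact enumeration and the reference oracle", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_warning(res <- wilcoxon_signed_rank(x, x), "zero")
  expect_equal(res$p, 1)

  withr::with_seed(32, {
    y20 <- rnorm(20)
    res20 <- wilcoxon_signed_rank(y20 + abs(rnorm(20)) + 0.1, y20)
    expect_equal(res20$W, 0)   # every x_i > y_i: smaller rank sum is zero

    for (i in 1:5) {
      a <- rnorm(6)
      b <- rnorm(6)
      got <- wilcoxon_signed_rank(a, b)
      ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
      expect_equal(got$p, ref$p.value, tolerance = 1e-12)
    }
    # tie-corrected normal approximation against the reference
    for (i in 1:3) {
      a <- round(rnorm(25), 1)
      b <- round(rnorm(25), 1)
      keep <- a != b
      got <- wilcoxon_signed_rank(a, b)
      ref <- stats::wilcox.test(a[keep], b[keep], paired = TRUE,
                                exact = FALSE, correct = FALSE)
      expect_equal(got$p, ref$p.value, tolerance = 1e-10)
    }
  })
})

test_that("BH correction reproduces the step-up definition", {
  expect_false(any(fdr_bh(rep(1, 6))$rejected))

  res <- fdr_bh(c(0.01, 0.02, 0.03, 0.5), q = 0.05)
  expect_equal(res$rejected, c(TRUE, TRUE, TRUE, FALSE))

  dup <- fdr_bh(c(0.04, 0.04, 0.2))
  expect_equal(dup$p_adjusted[1], dup$p_adjusted[2])

  withr::with_seed(33, {
    for (i in 1:20) {
      p <- runif(sample(3:12, 1))^2
      got <- fdr_bh(p, q = 0.1)
      oracle <- oracle_bh(p, q = 0.1)
      expect_equal(got$rejected, oracle$rejected)
      expect_equal(got$p_adjusted, oracle$adjusted, tolerance = 1e-12)
    }
  })
})

test_that("the interval-preserving shuffle keeps the gap multiset exactly", {
  two <- rep(0, 100); two[c(20, 50)] <- 1
  sh <- shuffle_preserving_ioi(two, seed = 1)
  expect_equal(diff(which(sh == 1)), 30)

  withr::with_seed(34, {
    v <- rep(0, 5000)
    v[sort(sample(5000, 50))] <- 1
  })
  sh2 <- shuffle_preserving_ioi(v, seed = 2)
  expect_equal(sum(sh2), 50)
  expect_equal(sort(diff(which(sh2 == 1))), sort(diff(which(v == 1))))
  expect_identical(shuffle_preserving_ioi(v, seed = 7),
                   shuffle_preserving_ioi(v, seed = 7))
})

test_that("the onset noise floor is calibrated on pure noise and exceeded by signal", {
  # pure-noise recordings: the true-onset score should fall inside the
  # shuffle CI in nearly all replicates
  inside <- vapply(1:20, function(i) {
    seeds <- withr::with_seed(400 + i, sample.int(.Machine$integer.max, 3))
    ev <- generate_event_train(30, 20, min_gap_s = 0.4, seed = seeds[1])
    eeg <- eeg_recording(pink_noise(3000, 2, seed = seeds[2]), 100)
    on <- events_to_markers(ev, 3000, 100)
    truth <- mean(trf_crossval(on, eeg, n_segments = 6,
                               lambda_grid = 1)$scores$score, na.rm = TRUE)
    nf <- suppressWarnings(
      onset_noise_floor(on, eeg, n_perm = 99, seed = seeds[3],
                        n_segments = 6, lambda_grid = 1))
    truth >= nf$ci_low && truth <= nf$ci_high
  }, logical(1))
  expect_gte(mean(inside), 0.9)

  # signal present: the true-onset score clears the upper CI bound
  sim <- quick_sim(60, 40, snr_db = 10, n_channels = 2, seed = 35)
  truth <- mean(trf_crossval(sim$onsets, sim$eeg, n_segments = 6,
                             lambda_grid = 1)$scores$score)
  nf <- onset_noise_floor(sim$onsets, sim$eeg, n_perm = 50, seed = 36,
                          lambda_grid = 1)
  expect_gt(truth, nf$ci_high)
  expect_length(nf$null_scores, 50)
})

test_that("time-cluster permutation finds injected effects and nothing else", {
  withr::with_seed(37, {
    base <- matrix(rnorm(12 * 61, sd = 0.05), 12, 61)
    same <- cluster_permutation_time(base, base, n_perm = 200, seed = 5)
    expect_equal(nrow(same), 0)

    cond_b <- base + matrix(rnorm(12 * 61, sd = 0.05), 12, 61)
    cond_b[, 31:41] <- cond_b[, 31:41] + 1    # effect at lag indices 31..41
    res <- cluster_permutation_time(base, cond_b, n_perm = 200, seed = 5)
    sig <- res[res$p < 0.05, ]
    expect_equal(nrow(sig), 1)
    expect_lte(sig$lag_start, 32)
    expect_gte(sig$lag_end, 40)
    # permutation p-values live on the k / n_perm grid
    expect_true(all(abs(res$p * 200 - round(res$p * 200)) < 1e-12))
  })
  expect_warning(
    cluster_permutation_time(matrix(rnorm(60), 6), matrix(rnorm(60), 6),
                             n_perm = 50, seed = 1),
    "coarse")
})
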