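test_that("event trains respect count, ordering and the minimum gap", {
  expect_equal(nrow(generate_event_train(60, 0, seed = 1)), 0)

  ev <- generate_event_train(600, 396, min_gap_s = 0.6, seed = 1)
  expect_equal(nrow(ev), 396)
  expect_false(is.unsorted(ev$onset_s))
  # exhaustive pairwise scan, not just adjacent gaps
  gaps <- abs(outer(ev$onset_s, ev$onset_s, "-"))
  expect_gte(min(gaps[upper.tri(gaps)]), 0.6)
  expect_lt(max(ev$onset_s), 600)

  ev2 <- generate_event_train(10, 5, min_gap_s = 1, seed = 7)
  g2 <- abs(outer(ev2$onset_s, ev2$onset_s, "-"))
  expect_gte(min(g2[upper.tri(g2)]), 1)

  expect_identical(generate_event_train(60, 20, seed = 3),
                   generate_event_train(60, 20, seed = 3))
  expect_error(generate_event_train(10, 30, min_gap_s = 1, seed = 1),
               "cannot place")
})

test_that("event categories and conditions follow the requested proportions", {
  ev <- generate_event_train(400, 90, min_gap_s = 0.3,
                             categories = c("a", "b", "c"),
                             condition_split = c(narrow = 0.5, wide = 0.5),
                             seed = 11)
  expect_equal(unname(table(ev$category)), rep(30L, 3), ignore_attr = TRUE)
  expect_equal(unname(table(ev$condition)), rep(45L, 2), ignore_attr = TRUE)
})

test_that("rendered soundscapes are RMS-matched and zero outside events", {
  silent <- render_soundscape(event_table(), list(), rate = 1000)
  expect_true(all(silent$samples == 0))

  # one 0.2 s tone at t = 1 s: support confined to [1.0, 1.2) s
  bank <- list(tone = sin(2 * pi * 50 * seq(0, 0.2 - 1e-3, by = 1e-3)))
  ev <- event_table(1.0, "tone")
  tr <- render_soundscape(ev, bank, 1000, duration_s = 2)
  nz <- which(tr$samples != 0)
  expect_gte(min(nz), 1001)
  expect_lte(max(nz), 1200)

  # two tones with RMS 0.1 and 0.3 each end up at the bank-average RMS 0.2
  mk <- function(a) a * sqrt(2) * sin(2 * pi * 40 * seq(0, 0.5 - 1e-3,
                                                        by = 1e-3))
  bank2 <- list(lo = mk(0.1), hi = mk(0.3))
  ev2 <- event_table(c(0, 1), c("lo", "hi"), duration_s = 0.5)
  tr2 <- render_soundscape(ev2, bank2, 1000, duration_s = 2)
  rms <- function(x) sqrt(mean(x^2))
  expect_equal(rms(tr2$samples[1:500]), 0.2, tolerance = 1e-6)
  expect_equal(rms(tr2$samples[1001:1500]), 0.2, tolerance = 1e-6)

  expect_error(render_soundscape(event_table(0, "mystery"), bank, 1000),
               "mystery")
})

test_that("soundscape support property holds for random event trains", {
  bank <- tone_bank(2000)
  for (seed in 1:3) {
    ev <- generate_event_train(30, 15, min_gap_s = 0.3, seed = seed)
    tr <- render_soundscape(ev, bank, 2000, duration_s = 30)
    covered <- rep(FALSE, length(tr$samples))
    for (i in seq_len(nrow(ev))) {
      len <- length(bank[[ev$category[i]]])
      i0 <- round(ev$onset_s[i] * 2000) + 1
      covered[i0:min(i0 + len - 1, length(covered))] <- TRUE
    }
    expect_true(all(tr$samples[!covered] == 0))
  }
})

test_that("triphasic kernels peak at the requested latencies", {
  z <- make_triphasic_kernel(100, peak_amplitudes = c(0, 0, 0))
  expect_true(all(z$amplitude == 0))

  k <- make_triphasic_kernel(100, c(0.05, 0.10, 0.20), c(1, -2, 1))
  expect_length(k$amplitude, 51)           # 0.5 s span at 100 Hz, both ends
  expect_equal(k$amplitude[1], 0)
  expect_equal(k$amplitude[51], 0)
  # local maxima at samples 5 and 20, minimum at sample 10 (0-based, +/- 1)
  maxima <- which(trfscape:::local_maxima(k$amplitude)) - 1
  expect_true(any(abs(maxima - 5) <= 1))
  expect_true(any(abs(maxima - 20) <= 1))
  expect_lte(abs(which.min(k$amplitude) - 1 - 10), 1)
  expect_gt(k$amplitude[6], 0)
  expect_lt(k$amplitude[11], 0)

  expect_error(make_triphasic_kernel(100, c(0.1, 0.05, 0.2)), "increasing")
  expect_error(make_triphasic_kernel(100, c(0.05, 0.1, 0.6), span_s = 0.6),
               "span_s")
})

test_that("pink noise has unit variance, a 1/f spectrum and independent channels", {
  x <- pink_noise(1e5, 2, seed = 1)
  expect_equal(apply(x, 2, var), c(1, 1), tolerance = 1e-10)
  expect_identical(pink_noise(512, 2, seed = 4), pink_noise(512, 2, seed = 4))

  # log-log periodogram slope over 1..40 Hz at a nominal 100 Hz rate
  n <- 2^20
  y <- pink_noise(n, 1, seed = 2)[, 1]
  spec <- Mod(fft(y))^2 / n
  freq <- (seq_len(n) - 1) * 100 / n
  band <- freq >= 1 & freq <= 40
  fit <- stats::lm(log(spec[band]) ~ log(freq[band]))
  expect_gt(coef(fit)[2], -1.2)
  expect_lt(coef(fit)[2], -0.8)

  # Independence: raw 1/f series have few effective low-frequency degrees
  # of freedom, so their sample correlation wanders on the order of 0.05
  # even for independent draws; the differenced (whitened) series gives a
  # sharp independence check.
  a <- pink_noise(1e5, 1, seed = 1)[, 1]
  b <- pink_noise(1e5, 1, seed = 2)[, 1]
  expect_lt(abs(cor(a, b)), 0.15)
  expect_lt(abs(cor(diff(a), diff(b))), 0.05)
  expect_lt(abs(cor(diff(x[, 1]), diff(x[, 2]))), 0.05)
})

test_that("noiseless synthesis equals the event-kernel convolution exactly", {
  k <- tiny_kernel()
  ev <- generate_event_train(30, 20, min_gap_s = 0.3, seed = 5)
  eeg <- synthesize_eeg(ev, k, Inf, n_channels = 3, eeg_rate = 100,
                        seed = 1, duration_s = 30)
  oracle <- oracle_event_convolution(ev, k, 3000, 100)
  for (ch in 1:3) expect_equal(eeg$data[, ch], oracle, ignore_attr = TRUE)
})

test_that("synthesis is linear in the event set and deterministic", {
  k <- tiny_kernel()
  ev <- generate_event_train(30, 20, min_gap_s = 0.3, seed = 6)
  a <- ev[seq(1, 20, by = 2), ]
  b <- ev[seq(2, 20, by = 2), ]
  full <- synthesize_eeg(ev, k, Inf, 1, 100, seed = 1, duration_s = 30)
  pa <- synthesize_eeg(a, k, Inf, 1, 100, seed = 1, duration_s = 30)
  pb <- synthesize_eeg(b, k, Inf, 1, 100, seed = 1, duration_s = 30)
  expect_equal(full$data, pa$data + pb$data, ignore_attr = TRUE)

  e1 <- synthesize_eeg(ev, k, 0, 2, 100, seed = 42, duration_s = 30)
  e2 <- synthesize_eeg(ev, k, 0, 2, 100, seed = 42, duration_s = 30)
  expect_identical(e1$data, e2$data)
  expect_error(synthesize_eeg(ev, k, NA, 2, 100, seed = 1), "snr_db")
})

test_that("an SNR grid yields one data set per level with monotone noise", {
  k <- tiny_kernel()
  ev <- generate_event_train(60, 40, min_gap_s = 0.6, seed = 2)
  grid <- seq(-30, 10, by = 5)
  sets <- lapply(grid, function(s) {
    synthesize_eeg(ev, k, s, 1, 100, seed = 3, duration_s = 60)
  })
  expect_length(sets, 9)
  sigmas <- vapply(sets, attr, numeric(1), "sigma_noise")
  expect_true(all(diff(sigmas) < 0))   # more noise at lower SNR
})

test_that("the trial-SNR estimator tracks high targets and saturates at its floor", {
  k <- tiny_kernel()
  ev <- generate_event_train(600, 396, min_gap_s = 0.6, seed = 1)
  # High SNR: empirical median within 2 dB of the 20 dB target.
  eeg20 <- synthesize_eeg(ev, k, 20, n_channels = 4, eeg_rate = 100,
                          seed = 2, duration_s = 600)
  est20 <- estimate_trial_snr(eeg20, ev)
  expect_lt(abs(median(est20$snr_db) - 20), 2)
  # Strong noise: the estimator cannot follow the nominal level; it reads
  # close to its analytic saturation floor instead.
  floor_db <- estimator_snr_floor(60000, 100)
  eeg30 <- synthesize_eeg(ev, k, -30, n_channels = 4, eeg_rate = 100,
                          seed = 3, duration_s = 600)
  est30 <- estimate_trial_snr(eeg30, ev)
  expect_lt(abs(median(est30$snr_db) - floor_db), 1.5)
  # Median reading is monotone non-decreasing in the nominal target.
  meds <- vapply(c(-10, 5, 20), function(s) {
    e <- synthesize_eeg(ev, k, s, n_channels = 2, eeg_rate = 100,
                        seed = 4, duration_s = 600)
    median(estimate_trial_snr(e, ev)$snr_db)
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})
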