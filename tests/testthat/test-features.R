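cfg <- feature_config()

test_that("energy novelty is zero on silence, peaks at energy steps and is flat in steady state", {
  rate <- 12800
  zero <- energy_novelty(audio_track(rep(0, 3 * rate), rate), cfg)
  expect_true(all(zero$data == 0))
  expect_equal(nrow(zero$data), 300)

  t <- seq(0, 6 - 1 / rate, by = 1 / rate)
  step <- audio_track(sin(2 * pi * 440 * t) * (t >= 3), rate)
  nov <- energy_novelty(step, cfg)
  t_peak <- (which.max(nov$data[, 1]) - 1) / 100
  # peak displacement is set by the log compression acting on the Hann
  # energy ramp (window 2048 / 12800 Hz = 160 ms): measured offset ~20 ms
  expect_lt(abs(t_peak - 3), 0.03)
  expect_true(all(nov$data >= 0))

  steady <- energy_novelty(audio_track(sin(2 * pi * 440 * t), rate), cfg)
  inner <- steady$data[50:550, 1]
  expect_lt(max(inner), 0.01 * max(nov$data[, 1]))
})

test_that("stereo audio is rejected with a mono instruction", {
  fake <- structure(list(samples = matrix(0, 100, 2), rate = 8000),
                    class = "audio_track")
  expect_error(energy_novelty(fake, cfg), "mono")
})

test_that("onset detection marks thresholded local maxima, first sample on plateaus", {
  expect_true(all(detect_onsets(rep(0, 50), 0.5, rate = 100)$data == 0))

  fs <- detect_onsets(c(0, 1, 0, 0, 3, 0), 0.5, rate = 100)
  expect_equal(which(fs$data[, 1] == 1), c(2L, 5L))  # 0-based samples 1, 4

  one <- detect_onsets(c(0, 0, 2, 0, 0), 1, rate = 100)
  expect_equal(sum(one$data), 1)

  plateau <- detect_onsets(c(0, 2, 2, 2, 0), 1, rate = 100)
  expect_equal(which(plateau$data[, 1] == 1), 2L)
  expect_true(fs$discrete)
})

test_that("onset count is monotone non-increasing in the threshold", {
  nov <- withr::with_seed(1, abs(cumsum(rnorm(500))) / 10)
  counts <- vapply(c(0.1, 0.5, 1, 2, 5),
                   function(th) sum(detect_onsets(nov, th, rate = 100)$data),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the Hilbert envelope recovers AM modulators and is homogeneous", {
  rate <- 8000
  tm <- seq(0, 4 - 1 / rate, by = 1 / rate)
  am <- (1 + 0.5 * sin(2 * pi * 2 * tm)) * sin(2 * pi * 1000 * tm)
  env <- hilbert_envelope(audio_track(am, rate), cfg)
  mod <- 1 + 0.5 * sin(2 * pi * 2 * (seq_len(nrow(env$data)) - 1) / 100)
  expect_gt(cor(env$data[, 1], mod), 0.99)

  expect_true(all(hilbert_envelope(audio_track(rep(0, rate), rate),
                                   cfg)$data == 0))

  env2 <- hilbert_envelope(audio_track(2 * am, rate), cfg)
  expect_equal(env2$data, 2 * env$data, tolerance = 1e-6)

  expect_error(hilbert_envelope(audio_track(rep(0.1, 5), rate), cfg),
               "warm-up")
})

test_that("the power envelope matches its closed forms", {
  rate <- 8000
  const <- power_envelope(audio_track(rep(0.5, rate), rate), cfg)
  expect_equal(unique(as.vector(const$data)), 0.25^log10(2),
               tolerance = 1e-12)

  expect_true(all(power_envelope(audio_track(rep(0, rate), rate),
                                 cfg)$data == 0))

  # exponent 0.5 reduces to the per-window RMS envelope
  x <- withr::with_seed(2, rnorm(rate))
  cfg_rms <- feature_config(power_compression_exponent = 0.5)
  got <- power_envelope(audio_track(x, rate), cfg_rms)
  oracle <- sqrt(colMeans(matrix(x^2, nrow = 80)))
  expect_equal(as.vector(got$data), oracle, tolerance = 1e-12)
})

test_that("the mel spectrogram localizes tones and has the EEG frame rate", {
  rate <- 12800
  zero <- mel_spectrogram(audio_track(rep(0, rate), rate), cfg)
  expect_true(all(zero$data == 0))
  expect_equal(dim(zero$data), c(100L, 40L))

  tone <- audio_track(sin(2 * pi * 440 * seq(0, 2 - 1 / rate, by = 1 / rate)),
                      rate)
  mel <- mel_spectrogram(tone, cfg)
  cf <- attr(mel, "center_freq_hz")
  expect_equal(unname(which.max(colSums(mel$data))),
               which.min(abs(cf - 440)))
  expect_true(all(mel$data >= 0))
  expect_equal(nrow(mel$data), round(2 * 100))

  cfg_bad <- feature_config(n_mels = 4000)
  expect_error(mel_spectrogram(tone, cfg_bad), "n_mels")
})

test_that("event markers place single ones at rounded onset samples", {
  ev <- event_table(c(1.0, 2.5), c("alarm", "alarm"),
                    condition = c("narrow", "wide"))
  mk <- events_to_markers(ev, 400, 100)
  expect_equal(which(mk$data[, "alarm"] == 1), c(101L, 251L))  # 0-based 100, 250
  expect_equal(sum(mk$data), 2)

  none <- events_to_markers(ev, 400, 100, categories = "beep")
  expect_true(all(none$data == 0))

  split <- events_to_markers(ev, 400, 100, condition_split = TRUE)
  expect_equal(split$names, c("alarm_narrow", "alarm_wide"))
  expect_equal(rowSums(split$data), as.vector(mk$data[, "alarm"]))

  clash <- event_table(c(1.0, 1.004), c("alarm", "alarm"))
  expect_error(events_to_markers(clash, 400, 100), "resolution limit")
  late <- event_table(5, "alarm")
  expect_error(events_to_markers(late, 400, 100), "before")
})

test_that("combining features min-max scales continuous columns and preserves binary ones", {
  n <- 201
  bin <- feature_set(withr::with_seed(3, rbinom(n, 1, 0.05)), 100,
                     names = "onsets", discrete = TRUE)
  env_vals <- seq(2, 6, length.out = n)
  env <- feature_set(env_vals, 100, names = "env", discrete = FALSE)

  both <- combine_features(bin, env)
  expect_equal(ncol(both$data), 2)
  expect_equal(both$discrete, c(TRUE, FALSE))
  expect_equal(both$data[, 1], bin$data[, 1], ignore_attr = TRUE)
  # value 4 with min 2 / max 6 lands on 0.5
  expect_equal(unname(both$data[which(env_vals == 4), 2]), 0.5)
  expect_true(all(both$data[, 2] >= 0 & both$data[, 2] <= 1))

  same <- combine_features(bin, bin)
  expect_equal(same$data[, 1], same$data[, 2], ignore_attr = TRUE)

  const <- feature_set(rep(3, n), 100, names = "flat", discrete = FALSE)
  expect_true(all(combine_features(const)$data == 0))

  short <- feature_set(rep(0, 100), 100, names = "s", discrete = TRUE)
  expect_error(combine_features(bin, short), "length")

  # combine-then-split restores binary columns bit-exactly
  expect_identical(both$data[, "onsets"], as.numeric(bin$data[, 1]),
                   ignore_attr = TRUE)
})

test_that("Hilbert and power envelopes agree on an AM fixture", {
  rate <- 8000
  tm <- seq(0, 6 - 1 / rate, by = 1 / rate)
  am <- (1 + 0.6 * sin(2 * pi * 3 * tm)) * sin(2 * pi * 800 * tm)
  h <- hilbert_envelope(audio_track(am, rate), cfg)
  p <- power_envelope(audio_track(am, rate), cfg)
  expect_gt(cor(h$data[, 1], p$data[, 1]), 0.9)
  expect_equal(nrow(h$data), nrow(p$data))
})

test_that("every acoustic feature lands on the same EEG sample grid", {
  rate <- 12800
  dur <- 3.7
  x <- withr::with_seed(4, rnorm(round(dur * rate)) * 0.1)
  au <- audio_track(x, rate)
  n_expected <- round(dur * 100)
  expect_equal(nrow(energy_novelty(au, cfg)$data), n_expected)
  expect_equal(nrow(hilbert_envelope(au, cfg)$data), n_expected)
  expect_equal(nrow(power_envelope(au, cfg)$data), n_expected)
  expect_equal(nrow(mel_spectrogram(au, cfg)$data), n_expected)
})

test_that("the default onset threshold recovers tone-bank events", {
  rate <- 12800
  ev <- generate_event_train(60, 40, min_gap_s = 0.6, seed = 5)
  au <- render_soundscape(ev, tone_bank(rate), rate, duration_s = 60)
  ons <- detect_onsets(energy_novelty(au, cfg), cfg$onset_threshold)
  detected_s <- (which(ons$data[, 1] == 1) - 1) / 100
  recovered <- vapply(ev$onset_s,
                      function(o) any(abs(detected_s - o) <= 0.05),
                      logical(1))
  expect_gte(mean(recovered), 0.95)
})
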