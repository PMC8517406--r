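# Amplitude of a sinusoid at frequency f in series x (Fourier projection).
sine_amplitude <- function(x, f, fs) {
  t <- (seq_along(x) - 1) / fs
  2 * abs(mean(x * exp(-2i * pi * f * t)))
}

test_that("recordings validate their inputs", {
  expect_error(continuous_recording(matrix(c(1, NA), 1), 1000), "NaN")
  rec <- continuous_recording(matrix(rnorm(100), 2), 500, c("a", "b"))
  expect_equal(rec$fs, 500)
  expect_equal(rec$channel_names, c("a", "b"))
})

test_that("resampling preserves in-band content and scales lengths", {
  fs <- 2034.5
  n <- round(fs * 30)
  t <- (seq_len(n) - 1) / fs
  rec <- continuous_recording(matrix(sin(2 * pi * 100 * t), 1), fs)
  out <- resample_to_analysis_rate(rec, 1000)
  expect_equal(out$fs, 1000)
  expect_lt(abs(ncol(out$samples) - n * 1000 / fs), 1.5)
  mid <- out$samples[1, 1000:(ncol(out$samples) - 1000)]
  expect_lt(abs(sine_amplitude(mid, 100, 1000) - 1), 0.01)
  # identity pass-through at equal rates
  same <- continuous_recording(matrix(rnorm(2000), 1), 1000)
  expect_identical(resample_to_analysis_rate(same, 1000), same)
  expect_error(resample_to_analysis_rate(same, 2000), "upsampling")
})

test_that("line-noise removal is narrowband and broadband-preserving", {
  fs <- 1000
  t <- (0:59999) / fs
  pure <- continuous_recording(matrix(sin(2 * pi * 60 * t), 1), fs)
  out <- remove_line_noise(pure)
  expect_lte(sd(out$samples[1, ]), 0.1 * sd(pure$samples[1, ]))
  # no-line input is passed through nearly unchanged
  set.seed(8)
  noise <- continuous_recording(matrix(rnorm(60000), 1), fs)
  out2 <- remove_line_noise(noise)
  rel <- sd(out2$samples[1, ] - noise$samples[1, ]) / sd(noise$samples[1, ])
  expect_lt(rel, 0.01)
  # 60 + 100 Hz mixture: 100 Hz amplitude preserved within 5%
  mix <- continuous_recording(
    matrix(sin(2 * pi * 60 * t) + 0.5 * sin(2 * pi * 100 * t), 1), fs)
  out3 <- remove_line_noise(mix)
  expect_lt(abs(sine_amplitude(out3$samples[1, ], 100, fs) - 0.5) / 0.5, 0.05)
  expect_lt(sine_amplitude(out3$samples[1, ], 60, fs), 0.05)
})

test_that("high-gamma bandpass has the specified passband and stopband", {
  fs <- 1000
  t <- (0:9999) / fs
  mid <- 2000:8000
  amp_after <- function(f) {
    rec <- continuous_recording(matrix(sin(2 * pi * f * t), 1), fs)
    sine_amplitude(bandpass_high_gamma(rec)$samples[1, mid], f, fs)
  }
  expect_gte(amp_after(110), 0.95)
  expect_lte(amp_after(30), 0.1)   # >= 20 dB attenuation
  dc <- bandpass_high_gamma(continuous_recording(matrix(rep(1, 10000), 1), fs))
  expect_lt(max(abs(dc$samples[1, mid])), 1e-6)
  wrong_rate <- continuous_recording(matrix(rnorm(1000), 1), 500)
  expect_error(bandpass_high_gamma(wrong_rate), "1000 Hz")
})

test_that("power envelope is the smoothed square with exact small cases", {
  fs <- 1000
  # 100 Hz sinusoid: 50 ms window = 5 full cycles, mean sin^2 = 0.5
  t <- (0:1999) / fs
  pw <- power_envelope(sin(2 * pi * 100 * t), fs)
  steady <- pw[100:1900]
  expect_true(all(abs(steady - 0.5) < 1e-3))
  expect_equal(power_envelope(numeric(500), fs), numeric(500))
  # impulse of height h: max output h^2 / window_samples
  x <- numeric(200); x[100] <- 3
  expect_equal(max(power_envelope(x, fs)), 9 / 50)
  expect_true(all(power_envelope(rnorm(300), fs) >= 0))
  expect_error(power_envelope(rnorm(10), 10, smooth_ms = 20), "window")
})

test_that("artifact detection masks exactly the contaminated trials", {
  set.seed(13)
  specs <- list(sequence_spec("aaaaa", "aaaai", 2, 10, 3))
  ev <- build_block(specs, start_gap_ms = 1000, randomize_order = FALSE)
  n <- max(ev$fifth_vowel_onset_ms) + 2000
  x <- rnorm(n)
  mask0 <- detect_artifact_trials(x, ev, 1000, k = 5)
  expect_true(all(!mask0) || mean(mask0) < 0.1)
  # inject a 10-sigma transient into trial 4's epoch
  idx <- ev$fifth_vowel_onset_ms[4] + 200
  x2 <- x; x2[idx] <- 10
  mask <- detect_artifact_trials(x2, ev, 1000, k = 5)
  expect_true(mask[4])
  expect_equal(sum(mask), sum(mask0) + !mask0[4])
  # k = Inf disables masking
  expect_false(any(detect_artifact_trials(x2, ev, 1000, k = Inf)))
  expect_error(detect_artifact_trials(numeric(0), ev, 1000), "empty")
})

test_that("Gaussian-only data stay under 2% masked trials at k = 5", {
  # Monte Carlo under the Gaussian null: per-trial masking probability is
  # P(any of 1400 samples beyond 5 sigma) ~ 1400 * 5.7e-7 ~ 0.08%
  set.seed(99)
  masked <- 0L
  total <- 0L
  specs <- list(sequence_spec("aaaaa", "aaaai", 0, 80, 20))
  for (r in 1:5) {
    ev <- build_block(specs, start_gap_ms = 500, randomize_order = FALSE)
    x <- rnorm(max(ev$fifth_vowel_onset_ms) + 1500)
    masked <- masked + sum(detect_artifact_trials(x, ev, 1000, k = 5))
    total <- total + nrow(ev)
  }
  expect_lt(masked / total, 0.02)
})

test_that("epoching aligns trials to the 5th-vowel onset", {
  specs <- list(sequence_spec("aaaaa", "aaaai", 2, 10, 3),
                sequence_spec("aaaai", "aaaaa", 2, 10, 3))
  ev <- build_block(specs, seed = 6, start_gap_ms = 1000)
  n <- max(ev$fifth_vowel_onset_ms) + 2000
  # constant power: every epoch identically constant
  ep <- epoch_power(rep(2.5, n), ev, 1000)
  expect_equal(nrow(ep$power), sum(!ev$is_habituation))
  expect_true(all(ep$power == 2.5))
  expect_equal(range(ep$time_ms), c(-600, 799))
  # time-locked marker lands at t = 0 in every epoch
  x <- numeric(n)
  x[lgdint:::ms_to_sample(ev$fifth_vowel_onset_ms, 1000)] <- 7
  ep2 <- epoch_power(x, ev, 1000)
  hit_col <- which(ep2$time_ms == 0)
  expect_true(all(ep2$power[, hit_col] == 7))
  expect_true(all(ep2$power[, -hit_col] == 0))
  # habituation-only schedule gives zero rows
  hab <- ev[ev$is_habituation, ]
  expect_equal(nrow(epoch_power(rep(1, n), hab, 1000)$power), 0)
  # out-of-bounds window names the trial
  expect_error(epoch_power(rep(1, 3000), ev, 1000), "trial")
})

test_that("recordings and epochs round-trip through the text containers", {
  rec <- continuous_recording(matrix(round(rnorm(400), 6), 2), 1000,
                              c("sA", "sB"))
  prefix <- file.path(withr::local_tempdir(), "rec")
  write_recording(rec, prefix)
  back <- read_recording(prefix)
  expect_equal(back$samples, rec$samples, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(back$fs, 1000)
  expect_equal(back$channel_names, c("sA", "sB"))

  ep <- simulate_null_epochs(3, seed = 2)
  prefix2 <- file.path(withr::local_tempdir(), "ep")
  write_power_epochs(ep, prefix2)
  ep_back <- read_power_epochs(prefix2)
  expect_equal(ep_back$power, ep$power, tolerance = 1e-12)
  expect_equal(ep_back$condition, ep$condition)
  expect_equal(ep_back$time_ms, ep$time_ms)
})

test_that("preprocessing pipeline is deterministic end to end", {
  ev <- build_block(list(sequence_spec("aaaaa", "aaaai", 2, 10, 3),
                         sequence_spec("aaaai", "aaaaa", 2, 10, 3)),
                    seed = 31, start_gap_ms = 1000)
  sim <- simulate_recording(ev, site_effect_spec(name = "s"), fs = 1000,
                            seed = 17)
  a <- preprocess_site(sim$recording, ev, 1)
  b <- preprocess_site(sim$recording, ev, 1)
  expect_identical(a$power, b$power)
  expect_identical(a$artifact, b$artifact)
  expect_true(all(a$power >= 0))
})
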