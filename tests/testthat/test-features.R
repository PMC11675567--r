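# Cycle detection, perturbation formulas, HNR, pitch, formants, duration,
# and feature-vector/table assembly.

test_that("cycle detection handles silence and out-of-range fundamentals", {
  expect_true(detect_periods(silence_wave())$unvoiced)
  expect_equal(detect_periods(silence_wave())$n, 0)
  # 100 Hz train searched above 150 Hz: fundamental outside the band
  train <- synthesize_vowel(voice_params(f0_hz = 100, duration_s = 1,
                                         formants_hz = NULL), seed = 1)
  s <- detect_periods(train, f0_min = 150, f0_max = 400)
  expect_true(s$unvoiced)
})

test_that("jitter variants match hand-computed values", {
  seq <- period_seq(periods = c(9, 11, 9, 11, 9) / 1000,
                    amplitudes = rep(1, 5))
  expect_equal(compute_jitter(seq, "local"), 2 / 9.8 * 100,
               tolerance = 1e-10)
  expect_equal(compute_jitter(seq, "absolute"), 0.002, tolerance = 1e-12)
  expect_equal(compute_jitter(seq, "rap"), (4 / 3) / 9.8 * 100,
               tolerance = 1e-10)
  expect_equal(compute_jitter(seq, "ppq5"), 0.8 / 9.8 * 100,
               tolerance = 1e-10)
  expect_equal(compute_jitter(seq, "ddp"), 4 / 9.8 * 100,
               tolerance = 1e-10)
  # constant sequence: all variants zero
  const <- period_seq(periods = rep(0.01, 12), amplitudes = rep(1, 12))
  for (v in jitter_variants()) expect_equal(compute_jitter(const, v), 0)
})

test_that("shimmer variants match hand-computed values", {
  seq <- period_seq(periods = rep(0.01, 5),
                    amplitudes = c(1.0, 1.2, 1.0, 1.2, 1.0))
  expect_equal(compute_shimmer(seq, "local"), 0.2 / 1.08 * 100,
               tolerance = 1e-10)
  expect_equal(compute_shimmer(seq, "apq3"), (0.4 / 3) / 1.08 * 100,
               tolerance = 1e-10)
  expect_equal(compute_shimmer(seq, "dda"), 0.4 / 1.08 * 100,
               tolerance = 1e-10)
  const <- period_seq(periods = rep(0.01, 15), amplitudes = rep(0.8, 15))
  for (v in shimmer_variants()) expect_equal(compute_shimmer(const, v), 0)
})

test_that("ddp = 3 rap and dda = 3 apq3 on random sequences", {
  for (k in 1:100) {
    s <- random_period_seq(n = sample(5:40, 1), seed = k)
    expect_equal(compute_jitter(s, "ddp"), 3 * compute_jitter(s, "rap"),
                 tolerance = 1e-12)
    expect_equal(compute_shimmer(s, "dda"), 3 * compute_shimmer(s, "apq3"),
                 tolerance = 1e-12)
  }
})

test_that("too few cycles and zero amplitudes yield reasoned missing values", {
  tiny <- period_seq(periods = c(0.01, 0.011), amplitudes = c(1, 1))
  r <- compute_jitter(tiny, "rap")
  expect_true(is.na(r))
  expect_equal(attr(r, "reason"), "too_few_cycles")
  expect_true(is.na(compute_jitter(tiny, "ppq5")))
  expect_true(is.na(compute_shimmer(tiny, "apq11")))
  withzero <- period_seq(periods = rep(0.01, 5),
                         amplitudes = c(1, 0, 1, 1, 1))
  db <- compute_shimmer(withzero, "local_db")
  expect_true(is.na(db))
  expect_equal(attr(db, "reason"), "zero_amplitude")
  expect_true(is.na(compute_jitter(period_seq(), "local")))
})

test_that("HNR closed form and waveform estimator behave", {
  expect_equal(hnr_from_decomposition(
    harmonic_decomposition(harmonic_energy = 100, noise_energy = 1)), 20)
  expect_equal(hnr_from_decomposition(
    harmonic_decomposition(harmonic_amplitudes = c(3, 4),
                           noise_energy = 25)), 0)
  expect_true(is.na(compute_hnr(silence_wave())))
  vals <- vapply(1:10, function(s) {
    compute_hnr(synthesize_vowel(
      voice_params(f0_hz = 100, duration_s = 0.8, noise_snr_db = 20),
      seed = s))
  }, numeric(1))
  expect_gt(mean(vals), 17)
  expect_lt(mean(vals), 23)
})

test_that("pitch tracking recovers constant and gliding fundamentals", {
  st <- f0_statistics(track_pitch(clean_vowel()))
  expect_equal(st$mean_f0, 100, tolerance = 0.01)
  expect_lt(st$stdev_f0, 1)

  # linear glide 100 -> 110 Hz (phase-accumulated sinusoid)
  fs <- 16000; t <- seq_len(fs) / fs
  f <- 100 + 10 * t
  glide <- waveform(0.8 * sin(2 * pi * cumsum(f) / fs), fs)
  gst <- f0_statistics(track_pitch(glide))
  expect_gt(gst$mean_f0, 103); expect_lt(gst$mean_f0, 107)

  expect_true(is.na(f0_statistics(track_pitch(silence_wave()))$mean_f0))
})

test_that("formant estimates recover the synthesis resonators", {
  targets <- c(700, 1200, 2600, 3400)
  fm <- formant_statistics(track_formants(clean_vowel()))
  for (k in 1:4) {
    expect_lt(abs(fm[[paste0("mean_f", k)]] - targets[k]) / targets[k], 0.10)
  }
  expect_equal(fm$avg_formant,
               mean(unlist(fm[paste0("mean_f", 1:4)])), tolerance = 1e-12)
  # pure white noise: no stable formant structure
  set.seed(9)
  noise <- waveform(0.5 * stats::runif(32000, -1, 1), 16000)
  fmn <- formant_statistics(track_formants(noise))
  expect_true(is.na(fmn$mean_f1))
})

test_that("duration measures active time against a -25 dB endpoint", {
  fs <- 16000
  tone <- 0.8 * sin(2 * pi * 150 * seq_len(2 * fs) / fs)
  padded <- waveform(c(numeric(fs / 2), tone, numeric(fs / 2)), fs)
  expect_equal(measure_duration(padded), 2, tolerance = 0.05)
  expect_equal(measure_duration(waveform(tone[1:fs], fs)), 1,
               tolerance = 0.05)
  expect_equal(measure_duration(silence_wave()), 0)
})

test_that("feature vectors have the full 23-entry catalogue", {
  expect_length(feature_names(), 23)
  fv <- extract_features(task_recording("a", clean_vowel(), "S1"))
  expect_length(fv, 23)
  expect_named(fv, feature_names())
  expect_false(anyNA(fv))

  sil <- extract_features(task_recording("a", silence_wave(), "S1"))
  expect_equal(sil[["duration"]], 0)
  expect_true(all(is.na(sil[setdiff(feature_names(), "duration")])))
  expect_true("unvoiced" %in% unlist(attr(sil, "missing_reasons")))
})

test_that("feature table assembly gives 184 stable columns", {
  expect_length(indicator_names(), 184)
  recs <- list()
  for (subj in c("A", "B")) for (task in task_ids()) {
    recs[[length(recs) + 1L]] <-
      task_recording(task, silence_wave(800, 8000), subj)
  }
  tab <- build_feature_table(recs)
  expect_equal(dim(tab), c(2, 185))
  expect_equal(names(tab), c("subject_id", indicator_names()))
  expect_true(all(tab[, grepl("__duration$", names(tab))] == 0))

  # duplicate (subject, task) is an input error
  expect_error(build_feature_table(c(recs, recs[1])), "duplicate")

  # byte-identical CSV across runs
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(tab, f1)
  write_feature_csv(build_feature_table(recs), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(names(read_feature_csv(f1)), names(tab))
})

test_that("relative measures are invariant to amplitude scaling", {
  w <- synthesize_vowel(voice_params(f0_hz = 100, duration_s = 0.8,
                                     jitter_pct = 1, shimmer_pct = 2),
                        seed = 5)
  half <- waveform(0.4 * w$samples / 0.9, w$sample_rate_hz)
  s1 <- detect_periods(w); s2 <- detect_periods(half)
  expect_equal(compute_jitter(s1, "local"), compute_jitter(s2, "local"),
               tolerance = 1e-6)
  expect_equal(compute_shimmer(s1, "local"), compute_shimmer(s2, "local"),
               tolerance = 1e-6)
  expect_equal(compute_hnr(w), compute_hnr(half), tolerance = 1e-6)
  expect_equal(f0_statistics(track_pitch(w))$mean_f0,
               f0_statistics(track_pitch(half))$mean_f0, tolerance = 1e-6)
})

test_that("silence padding shifts nothing but the duration endpoints", {
  w <- synthesize_vowel(voice_params(f0_hz = 120, duration_s = 0.6,
                                     jitter_pct = 1, sample_rate_hz = 16000),
                        seed = 8)
  pad <- waveform(c(numeric(4000), w$samples, numeric(4000)), 16000)
  expect_equal(compute_jitter(detect_periods(w), "local"),
               compute_jitter(detect_periods(pad), "local"),
               tolerance = 0.05)
  expect_equal(f0_statistics(track_pitch(w))$mean_f0,
               f0_statistics(track_pitch(pad))$mean_f0, tolerance = 0.01)
  expect_equal(measure_duration(pad), measure_duration(w),
               tolerance = 0.02)
})
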