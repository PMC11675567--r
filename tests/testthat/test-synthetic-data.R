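test_that("unperturbed pulse train has exact periods and is deterministic", {
  w <- clean_vowel()
  s <- detect_periods(w)
  expect_false(s$unvoiced)
  expect_gt(s$n, 90)
  expect_lt(max(abs(s$periods - 0.01)) / 0.01, 0.001)

  w2 <- synthesize_vowel(
    voice_params(f0_hz = 100, duration_s = 1, jitter_pct = 0,
                 shimmer_pct = 0, noise_snr_db = Inf), seed = 1)
  expect_identical(w$samples, w2$samples)
  # with perturbation active, different seeds give different signals
  pj <- voice_params(f0_hz = 100, duration_s = 1, jitter_pct = 1)
  expect_false(identical(synthesize_vowel(pj, seed = 1)$samples,
                         synthesize_vowel(pj, seed = 2)$samples))
  expect_identical(synthesize_vowel(pj, seed = 3)$samples,
                   synthesize_vowel(pj, seed = 3)$samples)
})

test_that("parameter validation rejects bad synthesis configs", {
  expect_error(voice_params(f0_hz = 30000, sample_rate_hz = 44100),
               "Nyquist")
  expect_error(voice_params(f0_hz = -1), "f0_hz")
  expect_error(voice_params(formants_hz = c(700, 600)), "increasing")
  expect_error(ddk_params(voice_params(f0_hz = 100), syllable_rate_hz = 60,
                          n_syllables = 5, gap_fraction = 0.5),
               "2 glottal cycles")
})

test_that("detected jitter on a 2% vowel lands in the spec band", {
  w <- synthesize_vowel(voice_params(f0_hz = 100, duration_s = 3,
                                     jitter_pct = 2, noise_snr_db = Inf),
                        seed = 11)
  j <- compute_jitter(detect_periods(w), "local")
  expect_gt(j, 1.5)
  expect_lt(j, 2.5)
  # the generator's own cycle list obeys the local-jitter formula
  gt <- attr(w, "ground_truth")
  j_gt <- mean(abs(diff(gt$periods))) / mean(gt$periods) * 100
  expect_lt(abs(j_gt - 2) / 2, 0.25)
})

test_that("generator calibration: ground-truth cycle statistics hit the targets", {
  # Eq-style local jitter/shimmer of the internal cycle lists, averaged
  # over 200 seeds, within 10% relative of the requested level
  for (level in c(0.5, 1, 2, 4)) {
    vals <- vapply(1:200, function(s) {
      gt <- attr(synthesize_vowel(
        voice_params(f0_hz = 100, duration_s = 1, jitter_pct = level,
                     shimmer_pct = level, formants_hz = NULL,
                     sample_rate_hz = 8000), seed = s), "ground_truth")
      c(mean(abs(diff(gt$periods))) / mean(gt$periods),
        mean(abs(diff(gt$amplitudes))) / mean(gt$amplitudes)) * 100
    }, numeric(2))
    expect_lt(abs(mean(vals[1, ]) - level) / level, 0.10)
    expect_lt(abs(mean(vals[2, ]) - level) / level, 0.10)
  }
})

test_that("measured HNR decreases strictly with injected noise power", {
  snrs <- c(30, 20, 10, 0)
  mean_hnr <- vapply(snrs, function(snr) {
    mean(vapply(1:20, function(s) {
      compute_hnr(synthesize_vowel(
        voice_params(f0_hz = 120, duration_s = 0.6, noise_snr_db = snr,
                     sample_rate_hz = 16000), seed = s))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_hnr) < 0))
})

test_that("DDK trains have the scheduled duration and gate structure", {
  dp <- ddk_params(voice_params(f0_hz = 120, duration_s = 2,
                                sample_rate_hz = 16000),
                   syllable_rate_hz = 5, n_syllables = 10,
                   gap_fraction = 0.4)
  w <- synthesize_ddk(dp, seed = 4)
  d <- measure_duration(w)
  expect_gt(d, 1.8); expect_lt(d, 2.2)
  expect_identical(w$samples, synthesize_ddk(dp, seed = 4)$samples)

  # gap_fraction = 0: no sub-threshold inter-syllable silence
  dp0 <- ddk_params(voice_params(f0_hz = 120, duration_s = 2,
                                 sample_rate_hz = 16000),
                    syllable_rate_hz = 5, n_syllables = 10,
                    gap_fraction = 0)
  w0 <- synthesize_ddk(dp0, seed = 4)
  fr <- matrix(w0$samples[1:(160 * floor(length(w0$samples) / 160))],
               nrow = 160)
  frms <- sqrt(colMeans(fr^2))
  expect_gt(min(frms), max(frms) * 10^(-25 / 20))
})

test_that("synthetic cohorts honour group sizes, labels and effect maps", {
  cohort <- generate_cohort(cohort_params(
    group_sizes = c(severe = 72, mild = 54, normal = 97),
    n_features = 10, seed = 1))
  expect_equal(nrow(cohort$roster), 223)
  expect_equal(as.vector(table(cohort$roster$group)), c(72, 54, 97))
  expect_true(all(assign_group(cohort$roster$kmmse) == cohort$roster$group))

  # single-group edge
  small <- generate_cohort(cohort_params(
    group_sizes = c(severe = 0, mild = 0, normal = 5),
    n_features = 4, seed = 2))
  expect_equal(nrow(small$features), 5)
  expect_true(all(small$roster$group == "normal"))

  # unknown indicator is a configuration error
  expect_error(cohort_params(effect_map = list(bogus__feature = c(severe = 1))),
               "unknown indicator")

  # determinism
  again <- generate_cohort(cohort_params(
    group_sizes = c(severe = 72, mild = 54, normal = 97),
    n_features = 10, seed = 1))
  expect_identical(cohort$features, again$features)
})

test_that("null cohorts show no spurious group differences", {
  # all effects zero: severe-vs-normal mean difference on an indicator is
  # non-significant at alpha = 0.01 in >= 95% of 100 simulated cohorts
  rejections <- vapply(1:100, function(s) {
    ch <- generate_cohort(cohort_params(
      group_sizes = c(severe = 30, mild = 0, normal = 30),
      n_features = 2, seed = s))
    x <- ch$features[[2]]
    g <- ch$roster$group
    stats::t.test(x[g == "severe"], x[g == "normal"])$p.value < 0.01
  }, logical(1))
  expect_lte(mean(rejections), 0.05)
})

test_that("WAV round trip preserves samples to 16-bit precision", {
  w <- synthesize_vowel(voice_params(f0_hz = 150, duration_s = 0.3,
                                     sample_rate_hz = 16000), seed = 3)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(w, path)
  r <- read_wav(path)
  expect_equal(r$sample_rate_hz, 16000)
  expect_equal(length(r$samples), length(w$samples))
  expect_lt(max(abs(r$samples - w$samples)), 1 / 32000)
})
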