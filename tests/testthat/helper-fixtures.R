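# Shared fixtures, built once per test run. Audio fixtures use reduced
# sample rates / durations where the assertion does not depend on them;
# anything asserting sub-percent timing accuracy uses the 44.1 kHz
# default.

fix <- new.env()

# clean 100 Hz vowel, no perturbation, no noise, default formants
clean_vowel <- function() {
  if (is.null(fix$clean)) {
    fix$clean <- synthesize_vowel(
      voice_params(f0_hz = 100, duration_s = 1, jitter_pct = 0,
                   shimmer_pct = 0, noise_snr_db = Inf), seed = 1)
  }
  fix$clean
}

silence_wave <- function(n = 16000, fs = 16000) waveform(numeric(n), fs)

# a small roster matching the study's printed group sizes
table1_roster <- function() {
  if (is.null(fix$roster)) {
    fix$roster <- generate_cohort(
      cohort_params(group_sizes = c(severe = 72, mild = 54, normal = 97),
                    n_features = 5, seed = 42))$roster
  }
  fix$roster
}

# random period sequences for formula-identity properties
random_period_seq <- function(n, seed) {
  set.seed(seed)
  period_seq(periods = 0.01 * (1 + 0.05 * stats::rnorm(n)),
             amplitudes = 1 + 0.1 * abs(stats::rnorm(n)))
}
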