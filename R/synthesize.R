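# Source-filter synthesis of vowel-like and DDK-like test signals.
#
# The glottal source is a band-limited impulse train: the sum of all
# harmonics of the (per-cycle) fundamental up to Nyquist/2.5, evaluated in
# closed form through the Dirichlet kernel so cost is O(n) regardless of
# harmonic count. Per-cycle period and amplitude multipliers (1 + eps_i)
# carry the jitter/shimmer perturbations; eps_i are i.i.d. Gaussian with
# sigma chosen so the local jitter/shimmer statistic of the generated cycle
# list equals the target in expectation (E|eps_i - eps_{i-1}| = 2 sigma /
# sqrt(pi)).

jitter_sigma <- function(pct) pct * sqrt(pi) / 200
# inverse of: 100 * E|P_i - P_{i-1}| / P0 = 100 * 2 sigma / sqrt(pi)

#' Synthesize a sustained vowel
#'
#' Generates a voiced, vowel-like waveform with known ground-truth
#' perturbations. The returned waveform carries a `ground_truth` attribute
#' with the per-cycle period and amplitude lists actually used, the pulse
#' times, and the realized noise level, so downstream estimators can be
#' validated against the generator itself.
#'
#' @param params A [voice_params()].
#' @param seed Integer seed; identical `params` + `seed` give bit-identical
#'   output.
#' @return A [waveform()] peak-normalized to 0.9, with attribute
#'   `ground_truth` (list: `periods`, `amplitudes`, `pulse_times`,
#'   `snr_db`).
#' @export
synthesize_vowel <- function(params, seed = 1L) {
  stopifnot(inherits(params, "voice_params"))
  fs <- params$sample_rate_hz
  withr_seed(seed, {
    n_total <- round(params$duration_s * fs)
    p0 <- 1 / params$f0_hz
    n_cycles_max <- ceiling(params$duration_s / p0 * 1.25) + 4L
    eps_p <- stats::rnorm(n_cycles_max, 0, jitter_sigma(params$jitter_pct))
    eps_a <- stats::rnorm(n_cycles_max, 0, jitter_sigma(params$shimmer_pct))
    periods <- p0 * pmax(0.2, 1 + eps_p)
    amps <- pmax(0.05, 1 + eps_a)
    ends <- cumsum(periods)
    n_cycles <- which(ends >= params$duration_s)[1]
    if (is.na(n_cycles)) n_cycles <- n_cycles_max
    periods <- periods[seq_len(n_cycles)]
    amps <- amps[seq_len(n_cycles)]
    boundaries <- c(0, cumsum(periods))

    # per-sample instantaneous frequency is piecewise-constant per cycle
    t <- (seq_len(n_total) - 1) / fs
    cyc <- findInterval(t, boundaries, rightmost.closed = TRUE)
    cyc[cyc < 1L] <- 1L
    cyc[cyc > n_cycles] <- n_cycles
    inst_f <- 1 / periods[cyc]
    phase <- 2 * pi * cumsum(inst_f) / fs
    n_harm <- max(1L, floor((fs / 2.5) / params$f0_hz))
    # the amplitude envelope is anchored at the pulse instants (one pulse
    # per cycle, at its end boundary) so each pulse's whole main lobe is
    # scaled by a single ground-truth amplitude
    pulse_t <- boundaries[-1]
    env <- if (n_cycles >= 2L) {
      stats::approx(pulse_t, amps, xout = t, rule = 2)$y
    } else rep(amps[1], n_total)
    src <- dirichlet_harmonics(phase, n_harm) * env

    noise <- if (is.finite(params$noise_snr_db)) stats::rnorm(n_total) else NULL

    if (!is.null(params$formants_hz)) {
      src <- resonator_cascade(src, params$formants_hz, params$formant_bw_hz, fs)
      if (!is.null(noise)) {
        noise <- resonator_cascade(noise, params$formants_hz,
                                   params$formant_bw_hz, fs)
      }
    }
    if (!is.null(noise)) {
      gain <- sqrt(mean(src^2) /
                   (mean(noise^2) * 10^(params$noise_snr_db / 10)))
      src <- src + gain * noise
    }
    src <- 0.9 * src / max(abs(src))
    out <- waveform(src, fs)
    attr(out, "ground_truth") <- list(
      periods = periods, amplitudes = amps,
      pulse_times = boundaries[-1], snr_db = params$noise_snr_db)
    out
  })
}

# sum_{k=1}^{K} cos(k * phi), via the Dirichlet kernel closed form.
dirichlet_harmonics <- function(phi, K) {
  half <- phi / 2
  denom <- sin(half)
  num <- sin(K * half) * cos((K + 1) * half)
  out <- num / denom
  degenerate <- abs(denom) < 1e-9
  if (any(degenerate)) out[degenerate] <- K
  out
}

#' Synthesize a DDK-style syllable train
#'
#' Gates a vowel-like carrier into `n_syllables` bursts at
#' `syllable_rate_hz`, with raised-cosine onset/offset ramps. Emulates
#' alternating/sequential motion rate recordings.
#'
#' @param params A [ddk_params()].
#' @param seed Integer seed.
#' @return A [waveform()]; attribute `ground_truth` adds the gate schedule
#'   (`syllable_onsets_s`, `syllable_offsets_s`) to the carrier's ground
#'   truth.
#' @export
synthesize_ddk <- function(params, seed = 1L) {
  stopifnot(inherits(params, "ddk_params"))
  total_s <- params$n_syllables / params$syllable_rate_hz
  base <- params$base
  base$duration_s <- total_s
  carrier <- synthesize_vowel(base, seed = seed)
  fs <- carrier$sample_rate_hz
  n <- length(carrier$samples)
  cycle_s <- 1 / params$syllable_rate_hz
  voiced_s <- (1 - params$gap_fraction) * cycle_s
  onsets <- (seq_len(params$n_syllables) - 1) * cycle_s
  offsets <- onsets + voiced_s
  gate <- numeric(n)
  t <- (seq_len(n) - 1) / fs
  ramp_s <- min(0.005, voiced_s / 4)
  for (i in seq_len(params$n_syllables)) {
    inside <- t >= onsets[i] & t < offsets[i]
    g <- numeric(sum(inside))
    tt <- t[inside] - onsets[i]
    g[] <- 1
    up <- tt < ramp_s
    g[up] <- 0.5 - 0.5 * cos(pi * tt[up] / ramp_s)
    down <- tt > voiced_s - ramp_s
    g[down] <- 0.5 - 0.5 * cos(pi * (voiced_s - tt[down]) / ramp_s)
    gate[inside] <- g
  }
  y <- carrier$samples * gate
  peak <- max(abs(y))
  if (peak > 0) y <- 0.9 * y / peak
  out <- waveform(y, fs)
  gt <- attr(carrier, "ground_truth")
  gt$syllable_onsets_s <- onsets
  gt$syllable_offsets_s <- offsets
  attr(out, "ground_truth") <- gt
  out
}

# Evaluate an expression under a local, restored RNG state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
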