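#' Vowel synthesis parameters
#'
#' Parameters for the source-filter sustained-vowel generator. The source
#' is a band-limited glottal pulse train whose per-cycle period and
#' amplitude are perturbed to hit target jitter and shimmer levels; white
#' noise is mixed in at a target harmonics-to-noise ratio and the result is
#' shaped by second-order formant resonators.
#'
#' @param f0_hz Fundamental frequency in Hz (> 0).
#' @param duration_s Duration in seconds (> 0).
#' @param sample_rate_hz Sampling rate, samples/s. Default 44100.
#' @param jitter_pct Target cycle-to-cycle period perturbation, percent
#'   (local jitter of the generated period sequence, in expectation).
#' @param shimmer_pct Target cycle-to-cycle amplitude perturbation, percent.
#' @param noise_snr_db Harmonic-to-noise energy ratio in dB over the voiced
#'   portion; `Inf` means no noise.
#' @param formants_hz Ordered vector of 1-4 resonance centre frequencies
#'   (Hz), strictly increasing. `NULL` disables the filter.
#' @param formant_bw_hz Resonator bandwidths (Hz), recycled to match
#'   `formants_hz`.
#' @return A validated list of class `voice_params`.
#' @export
voice_params <- function(f0_hz = 100, duration_s = 2, sample_rate_hz = 44100,
                         jitter_pct = 0, shimmer_pct = 0, noise_snr_db = Inf,
                         formants_hz = c(700, 1200, 2600, 3400),
                         formant_bw_hz = c(80, 100, 160, 200)) {
  stopifnot(f0_hz > 0, duration_s > 0, sample_rate_hz > 0,
            jitter_pct >= 0, shimmer_pct >= 0)
  if (f0_hz >= sample_rate_hz / 2) {
    stop("f0_hz must be below the Nyquist frequency", call. = FALSE)
  }
  if (!is.null(formants_hz)) {
    if (length(formants_hz) < 1L || length(formants_hz) > 4L) {
      stop("formants_hz must list 1-4 resonances", call. = FALSE)
    }
    if (any(diff(formants_hz) <= 0)) {
      stop("formant frequencies must be strictly increasing", call. = FALSE)
    }
    formant_bw_hz <- rep_len(formant_bw_hz, length(formants_hz))
  }
  structure(list(f0_hz = f0_hz, duration_s = duration_s,
                 sample_rate_hz = sample_rate_hz, jitter_pct = jitter_pct,
                 shimmer_pct = shimmer_pct, noise_snr_db = noise_snr_db,
                 formants_hz = formants_hz, formant_bw_hz = formant_bw_hz),
            class = "voice_params")
}

#' DDK synthesis parameters
#'
#' Parameters for diadochokinetic (rapid syllable repetition) recordings:
#' a vowel-like carrier gated into syllable bursts.
#'
#' @param base A [voice_params()] for the carrier.
#' @param syllable_rate_hz Syllables per second (> 0).
#' @param n_syllables Number of syllables (>= 1).
#' @param gap_fraction Silent fraction of each syllable cycle, in `[0, 1)`.
#' @return A validated list of class `ddk_params`.
#' @export
ddk_params <- function(base = voice_params(duration_s = 2),
                       syllable_rate_hz = 5, n_syllables = 10,
                       gap_fraction = 0.4) {
  stopifnot(inherits(base, "voice_params"), syllable_rate_hz > 0,
            n_syllables >= 1, gap_fraction >= 0, gap_fraction < 1)
  voiced_s <- (1 - gap_fraction) / syllable_rate_hz
  if (voiced_s < 2 / base$f0_hz) {
    stop("voiced part of each syllable must span at least 2 glottal cycles",
         call. = FALSE)
  }
  structure(list(base = base, syllable_rate_hz = syllable_rate_hz,
                 n_syllables = n_syllables, gap_fraction = gap_fraction),
            class = "ddk_params")
}

#' Cohort simulation parameters
#'
#' Describes a synthetic study cohort: group sizes for the three
#' cognitive-status groups, optional per-indicator group mean shifts (in
#' units of the within-group standard deviation), and an equicorrelated
#' noise model.
#'
#' @param group_sizes Named or positional counts for (severe, mild, normal).
#' @param effect_map Named list: indicator name -> named numeric vector of
#'   per-group mean shifts in SD units, e.g.
#'   `list(a__jitter_local = c(severe = 1.5, mild = 0.8))`. Groups not named
#'   get shift 0.
#' @param n_features Total indicator count (default 184, the full
#'   8-task x 23-feature catalogue).
#' @param base_correlation Common pairwise correlation of the noise in
#'   `[0, 1)`.
#' @param seed Integer seed.
#' @return A validated list of class `cohort_params`.
#' @export
cohort_params <- function(group_sizes = c(severe = 72, mild = 54, normal = 97),
                          effect_map = list(), n_features = 184,
                          base_correlation = 0.2, seed = 1L) {
  if (is.null(names(group_sizes))) {
    names(group_sizes) <- c("severe", "mild", "normal")
  }
  stopifnot(setequal(names(group_sizes), c("severe", "mild", "normal")),
            all(group_sizes >= 0), n_features >= 1,
            base_correlation >= 0, base_correlation < 1)
  group_sizes <- group_sizes[c("severe", "mild", "normal")]
  nm <- indicator_names(n_features)
  bad <- setdiff(names(effect_map), nm)
  if (length(bad)) {
    stop("effect_map names unknown indicator(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(group_sizes = group_sizes, effect_map = effect_map,
                 n_features = n_features,
                 base_correlation = base_correlation,
                 seed = as.integer(seed)),
            class = "cohort_params")
}
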