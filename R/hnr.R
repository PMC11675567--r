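# Harmonics-to-noise ratio. The definitional contract is the closed form
# 10*log10(harmonic energy / noise energy) on a harmonic decomposition;
# the waveform estimator is the framewise normalized-autocorrelation form
# (r at the period lag; frame HNR = 10*log10(r/(1-r))), the standard
# practice in clinical voice analysis.

#' Harmonic decomposition container
#'
#' Energies of the harmonic (periodic) and noise (aperiodic) parts of a
#' signal; the harmonic energy is the sum of squared harmonic amplitudes.
#'
#' @param harmonic_amplitudes Amplitudes H_n of the first N harmonics, or
#'   `NULL` if `harmonic_energy` is given directly.
#' @param noise_energy Residual (noise) energy, >= 0.
#' @param harmonic_energy Total harmonic energy; computed as
#'   `sum(harmonic_amplitudes^2)` when amplitudes are supplied.
#' @param f0_hz Fundamental frequency in Hz.
#' @return Object of class `harmonic_decomposition`.
#' @export
harmonic_decomposition <- function(harmonic_amplitudes = NULL,
                                   noise_energy,
                                   harmonic_energy = NULL,
                                   f0_hz = NA_real_) {
  if (is.null(harmonic_energy)) {
    stopifnot(!is.null(harmonic_amplitudes), length(harmonic_amplitudes) >= 1)
    harmonic_energy <- sum(harmonic_amplitudes^2)
  }
  stopifnot(harmonic_energy >= 0, noise_energy >= 0)
  structure(list(harmonic_energy = harmonic_energy,
                 noise_energy = noise_energy,
                 n_harmonics = length(harmonic_amplitudes),
                 f0_hz = f0_hz),
            class = "harmonic_decomposition")
}

#' @rdname compute_hnr
#' @export
hnr_from_decomposition <- function(decomp) {
  stopifnot(inherits(decomp, "harmonic_decomposition"))
  10 * log10(decomp$harmonic_energy / decomp$noise_energy)
}

#' Harmonics-to-noise ratio of a waveform
#'
#' Per voiced frame, the Boersma-normalized autocorrelation `r` at the
#' detected period lag estimates the fraction of periodic energy; the
#' frame HNR is `10*log10(r/(1-r))` and the result is the mean over voiced
#' frames, capped at +40 dB. `hnr_from_decomposition()` applies the
#' closed-form definition to known harmonic/noise energies.
#'
#' @param wave A [waveform()].
#' @param f0_min,f0_max Pitch search range, Hz.
#' @param decomp A [harmonic_decomposition()].
#' @return HNR in dB, or `NA` (reason `"unvoiced"`) when no voiced frame is
#'   found.
#' @export
compute_hnr <- function(wave, f0_min = 60, f0_max = 400) {
  # 80 ms frames: the acf peak needs several periods per frame for the
  # r/(1-r) ratio to be stable near r ~ 1 (40 ms frames bias HNR upward)
  pf <- pitch_frames(wave, f0_min, f0_max, frame_s = 0.08)
  if (is.null(pf) || !any(pf$voiced)) return(missing_value("unvoiced"))
  r <- pf$r[pf$voiced]
  r <- pmin(r, 1 - 1e-4)  # cap at +40 dB
  frame_hnr <- 10 * log10(r / (1 - r))
  mean(pmin(frame_hnr, 40))
}
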