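# Fundamental-frequency tracking and its summary statistics.

#' Track the fundamental frequency
#'
#' Framewise autocorrelation pitch tracking (40 ms Hann frames, 10 ms
#' hop). F0 values are only reported for voiced frames and always lie in
#' `[f0_min, f0_max]`.
#'
#' @param wave A [waveform()].
#' @param f0_min,f0_max Search range, Hz.
#' @return An object of class `pitch_track`: data.frame with columns
#'   `time` (s), `voiced` (logical), `f0_hz` (NA for unvoiced frames).
#' @export
track_pitch <- function(wave, f0_min = 60, f0_max = 400) {
  pf <- pitch_frames(wave, f0_min, f0_max)
  if (is.null(pf)) {
    pf <- data.frame(time = numeric(), voiced = logical(),
                     period_s = numeric(), r = numeric())
  }
  out <- data.frame(time = pf$time, voiced = pf$voiced,
                    f0_hz = ifelse(pf$voiced, 1 / pf$period_s, NA_real_))
  out$f0_hz <- pmin(pmax(out$f0_hz, f0_min), f0_max)
  class(out) <- c("pitch_track", "data.frame")
  out
}

#' F0 summary statistics
#'
#' Mean and standard deviation (n-1 denominator) of F0 over voiced frames
#' only.
#'
#' @param track A [track_pitch()] result.
#' @return List with `mean_f0` and `stdev_f0` (Hz); `NA` with a reason
#'   attribute when there is no voiced frame (mean) or a single voiced
#'   frame (stdev).
#' @export
f0_statistics <- function(track) {
  stopifnot(inherits(track, "pitch_track"))
  f0 <- track$f0_hz[track$voiced]
  if (!length(f0)) {
    return(list(mean_f0 = missing_value("unvoiced"),
                stdev_f0 = missing_value("unvoiced")))
  }
  list(mean_f0 = mean(f0),
       stdev_f0 = if (length(f0) >= 2L) stats::sd(f0)
                  else missing_value("single_frame"))
}
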