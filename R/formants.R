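# Formant (vocal-tract resonance) estimation by linear prediction:
# resample to 10 kHz, pre-emphasize, 25 ms frames, LPC order 10 via
# Levinson-Durbin on the frame autocorrelation, roots of the prediction
# polynomial -> resonance frequencies and bandwidths; keep roots with
# bandwidth < 400 Hz and assign the lowest four by frequency.

# Levinson-Durbin recursion: autocorrelation r[0..p] -> LPC coefficients
# a[1..p] of the prediction polynomial 1 - sum a_k z^-k.
levinson_durbin <- function(r, p) {
  a <- numeric(p)
  e <- r[1]
  if (e <= 0) return(NULL)
  for (i in seq_len(p)) {
    acc <- r[i + 1]
    if (i > 1) acc <- acc - sum(a[seq_len(i - 1)] * r[i:2])
    k <- acc / e
    new_a <- a
    new_a[i] <- k
    if (i > 1) new_a[seq_len(i - 1)] <- a[seq_len(i - 1)] - k * a[(i - 1):1]
    a <- new_a
    e <- e * (1 - k^2)
    if (e <= 0) return(NULL)
  }
  a
}

lpc_resonances <- function(frame, fs, order = 10L, max_bw = 400) {
  n <- length(frame)
  fr <- frame * hann_window(n)
  r <- vapply(0:order, function(k) sum(fr[1:(n - k)] * fr[(1 + k):n]),
              numeric(1))
  if (r[1] <= 0) return(NULL)
  a <- levinson_durbin(r, order)
  if (is.null(a)) return(NULL)
  rts <- polyroot(c(1, -a))
  rts <- rts[Im(rts) > 0.01]
  if (!length(rts)) return(NULL)
  freq <- Arg(rts) * fs / (2 * pi)
  bw <- -log(Mod(rts)) * fs / pi
  keep <- bw < max_bw & freq > 90 & freq < fs / 2 - 100
  if (!any(keep)) return(NULL)
  ord <- order(freq[keep])
  data.frame(freq = freq[keep][ord], bw = bw[keep][ord])
}

#' Track formant frequencies
#'
#' Per-frame F1-F4 estimates over the voiced part of a recording. Frames
#' where fewer than four resonances survive the bandwidth filter are
#' dropped.
#'
#' @param wave A [waveform()].
#' @param order LPC order (default 8 at the internal 10 kHz rate: one
#'   pole pair per tracked formant; higher orders admit spurious poles
#'   on strongly harmonic signals).
#' @param preemphasis Pre-emphasis coefficient (default 0.97).
#' @return An object of class `formant_track`: data.frame with `time` and
#'   `f1`..`f4` (Hz); zero rows when no frame is usable.
#' @export
track_formants <- function(wave, order = 8L, preemphasis = 0.97) {
  wave <- as_waveform(wave)
  w10 <- resample_wave(wave, 10000)
  fs <- w10$sample_rate_hz
  x <- w10$samples
  x <- c(x[1], x[-1] - preemphasis * x[-length(x)])
  frame_len <- round(0.025 * fs)
  hop <- round(0.010 * fs)
  frames <- frame_signal(x, frame_len, hop)
  empty <- structure(data.frame(time = numeric(), f1 = numeric(),
                                f2 = numeric(), f3 = numeric(),
                                f4 = numeric()),
                     class = c("formant_track", "data.frame"))
  if (is.null(frames)) return(empty)
  # voicing gate from the pitch tracker on the resampled signal
  pf <- pitch_frames(w10, 60, 400)
  if (is.null(pf) || !any(pf$voiced)) return(empty)
  voiced_at <- stats::approxfun(pf$time, as.numeric(pf$voiced),
                                method = "constant", rule = 2)
  times <- ((seq_len(ncol(frames)) - 1) * hop + frame_len / 2) / fs
  rows <- lapply(seq_along(times), function(j) {
    if (voiced_at(times[j]) < 0.5) return(NULL)
    res <- lpc_resonances(frames[, j], fs, order)
    if (is.null(res) || nrow(res) < 4L) return(NULL)
    c(times[j], res$freq[1:4])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  m <- do.call(rbind, rows)
  out <- data.frame(time = m[, 1], f1 = m[, 2], f2 = m[, 3],
                    f3 = m[, 4], f4 = m[, 5])
  class(out) <- c("formant_track", "data.frame")
  out
}

#' Formant summary statistics
#'
#' Mean and median of each of F1-F4 over retained frames, plus the average
#' formant (arithmetic mean of the four per-formant means).
#'
#' @param track A [track_formants()] result.
#' @return Named list: `mean_f1`..`mean_f4`, `median_f1`..`median_f4`,
#'   `avg_formant`; all `NA` with a reason attribute when no frame was
#'   retained.
#' @export
formant_statistics <- function(track) {
  stopifnot(inherits(track, "formant_track"))
  nms <- c(paste0("mean_f", 1:4), paste0("median_f", 1:4), "avg_formant")
  if (!nrow(track)) {
    out <- lapply(nms, function(x) missing_value("no_formant_frames"))
    names(out) <- nms
    return(out)
  }
  means <- vapply(track[paste0("f", 1:4)], mean, numeric(1))
  medians <- vapply(track[paste0("f", 1:4)], stats::median, numeric(1))
  out <- as.list(c(means, medians, mean(means)))
  names(out) <- nms
  out
}
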