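# Glottal cycle detection: framewise autocorrelation voicing/period
# estimation, then time-domain peak picking refined by parabolic
# interpolation. The user-facing contract is the PeriodSequence (per-cycle
# durations P_i and peak amplitudes A_i) feeding the jitter/shimmer
# formulas.

#' Period sequence constructor
#'
#' Per-cycle durations and amplitudes extracted from a voiced waveform
#' (or built directly, e.g. for formula tests).
#'
#' @param periods Cycle durations P_i in seconds (all > 0).
#' @param amplitudes Per-cycle peak amplitudes A_i (same length, all >= 0).
#' @param unvoiced Flag: `TRUE` when no voiced stretch was found.
#' @param peak_times Optional pulse times (seconds) the cycles were cut at.
#' @param segment Optional integer id of the voiced segment each cycle
#'   belongs to (DDK recordings have several).
#' @return An object of class `period_seq` with fields `periods`,
#'   `amplitudes`, `n`, `mean_period`, `mean_amplitude`, `unvoiced`.
#' @export
period_seq <- function(periods = numeric(), amplitudes = numeric(),
                       unvoiced = length(periods) == 0L,
                       peak_times = NULL, segment = NULL) {
  stopifnot(length(periods) == length(amplitudes),
            all(periods > 0), all(amplitudes >= 0))
  structure(list(periods = as.numeric(periods),
                 amplitudes = as.numeric(amplitudes),
                 n = length(periods),
                 mean_period = if (length(periods)) mean(periods) else NA_real_,
                 mean_amplitude = if (length(amplitudes)) mean(amplitudes) else NA_real_,
                 unvoiced = unvoiced,
                 peak_times = peak_times,
                 segment = segment),
            class = "period_seq")
}

#' @export
print.period_seq <- function(x, ...) {
  if (x$unvoiced) {
    cat("<period_seq: unvoiced>\n")
  } else {
    cat(sprintf("<period_seq: %d cycles, mean period %.4f ms>\n",
                x$n, 1000 * x$mean_period))
  }
  invisible(x)
}

# Framewise voicing and period estimate. Returns data.frame with one row
# per frame: time (centre, s), voiced, period_s (NA if unvoiced), r.
pitch_frames <- function(wave, f0_min = 60, f0_max = 400,
                         frame_s = 0.04, hop_s = 0.01,
                         voicing_threshold = 0.45) {
  wave <- as_waveform(wave)
  fs <- wave$sample_rate_hz
  stopifnot(f0_min > 0, f0_min < f0_max, f0_max < fs / 2)
  frame_len <- round(frame_s * fs)
  hop <- max(1L, round(hop_s * fs))
  frames <- frame_signal(wave$samples, frame_len, hop)
  if (is.null(frames)) return(NULL)
  lag_min <- max(2L, floor(fs / f0_max))
  lag_max <- ceiling(fs / f0_min)
  if (lag_max >= frame_len - 1L) lag_max <- frame_len - 2L
  if (lag_min >= lag_max) return(NULL)
  win <- hann_window(frame_len)
  wacf <- window_acf_table(win, lag_max + 1L)
  n_frames <- ncol(frames)
  times <- ((seq_len(n_frames) - 1) * hop + frame_len / 2) / fs
  voiced <- logical(n_frames)
  period <- rep(NA_real_, n_frames)
  rbest <- numeric(n_frames)
  # global amplitude floor: silent frames are never voiced
  peak_rms <- max(apply(frames, 2, rms))
  for (j in seq_len(n_frames)) {
    fr <- frames[, j]
    if (peak_rms <= 0 || rms(fr) < 1e-3 * peak_rms) next
    r <- normalized_acf(fr, win, wacf, lag_max + 1L)
    seg <- r[(lag_min + 1L):(lag_max + 1L)]  # r[k+1] is lag k
    # among near-maximal local peaks prefer the shortest lag: a periodic
    # signal has r(P) ~ r(2P) ~ 1 and the raw argmax would often pick the
    # octave below (classic subharmonic error)
    loc <- which(seg >= c(seg[-1], -Inf) & seg >= c(-Inf, seg[-length(seg)]))
    if (!length(loc)) loc <- which.max(seg)
    cand <- loc[seg[loc] >= 0.9 * max(seg[loc])]
    k <- cand[1]
    rmax <- seg[k]
    lag <- lag_min + k - 1L
    if (is.finite(rmax) && rmax >= voicing_threshold) {
      # parabolic refinement of the acf peak
      if (lag > lag_min && lag < lag_max) {
        pp <- parabolic_peak(r[lag], r[lag + 1L], r[lag + 2L])
        lag_ref <- lag + pp$offset
        rmax <- min(1, pp$value)
      } else lag_ref <- lag
      voiced[j] <- TRUE
      period[j] <- lag_ref / fs
      rbest[j] <- min(1, max(0, rmax))
    }
  }
  data.frame(time = times, voiced = voiced, period_s = period, r = rbest)
}

#' Detect glottal cycles
#'
#' Locates cycle boundaries by framewise autocorrelation peak picking in
#' the period band `[1/f0_max, 1/f0_min]`, refines them to waveform peaks
#' (sub-sample, by parabolic interpolation) and returns the per-cycle
#' duration and peak-amplitude sequence. Unvoiced stretches are excluded;
#' cycles from different voiced segments carry a segment id so DDK
#' perturbation statistics can be computed within segments.
#'
#' @param wave A [waveform()].
#' @param f0_min,f0_max Pitch search range in Hz; defaults 60-400
#'   (elderly-adult range).
#' @param voicing_threshold Minimum normalized autocorrelation for a frame
#'   to count as voiced (default 0.45).
#' @return A [period_seq()]; `unvoiced = TRUE` with `n = 0` when no voiced
#'   frame is found (silence, noise, or fundamental outside the range).
#' @export
detect_periods <- function(wave, f0_min = 60, f0_max = 400,
                           voicing_threshold = 0.45) {
  wave <- as_waveform(wave)
  fs <- wave$sample_rate_hz
  pf <- pitch_frames(wave, f0_min, f0_max,
                     voicing_threshold = voicing_threshold)
  if (is.null(pf) || !any(pf$voiced)) return(period_seq())
  x <- wave$samples
  vi <- which(pf$voiced)
  # contiguous voiced frame runs -> voiced segments
  runs <- split(vi, cumsum(c(1L, diff(vi) != 1L)))
  all_periods <- numeric(0); all_amps <- numeric(0)
  all_times <- numeric(0); all_seg <- integer(0)
  seg_id <- 0L
  for (run in runs) {
    t0 <- pf$time[run[1]] - 0.02
    t1 <- pf$time[run[length(run)]] + 0.02
    i0 <- max(1L, floor(t0 * fs)); i1 <- min(length(x), ceiling(t1 * fs))
    per_of <- if (length(run) >= 2L) {
      stats::approxfun(pf$time[run], pf$period_s[run], rule = 2)
    } else {
      local({ p <- pf$period_s[run]; function(t) rep(p, length(t)) })
    }
    # anchor at the strongest positive peak inside the segment
    seg_idx <- i0:i1
    anchor <- seg_idx[which.max(x[seg_idx])]
    peaks <- walk_peaks(x, fs, anchor, per_of, i0, i1)
    if (length(peaks) < 3L) next
    seg_id <- seg_id + 1L
    periods <- diff(peaks) / fs
    # guard against octave slips / gap-bridging: drop cycles far from the
    # frame estimate
    est <- per_of((peaks[-1] + peaks[-length(peaks)]) / 2 / fs)
    ok <- periods > 0.7 * est & periods < 1.4 * est
    # cycle amplitude = band-limited interpolated height of the cycle's
    # leading pulse. (The interval max would see both endpoint pulses and
    # report max(A_i, A_{i+1}), halving measured shimmer; sample maxima or
    # 3-point parabolas on narrow pulses fluctuate with grid alignment.)
    amp <- vapply(seq_along(periods), function(i) {
      sinc_peak_height(x, peaks[i])
    }, numeric(1))
    all_periods <- c(all_periods, periods[ok])
    all_amps <- c(all_amps, amp[ok])
    all_times <- c(all_times, peaks[-length(peaks)][ok] / fs)
    all_seg <- c(all_seg, rep(seg_id, sum(ok)))
  }
  if (!length(all_periods)) return(period_seq())
  # trim ramp cycles at segment edges: onset/offset cycles have gated
  # amplitudes and unreliable first periods
  keep <- rep(TRUE, length(all_periods))
  for (s in unique(all_seg)) {
    idx <- which(all_seg == s)
    med <- stats::median(all_amps[idx])
    lo <- idx[1]; hi <- idx[length(idx)]
    while (lo < hi && all_amps[lo] < 0.7 * med) { keep[lo] <- FALSE; lo <- lo + 1L }
    while (hi > lo && all_amps[hi] < 0.7 * med) { keep[hi] <- FALSE; hi <- hi - 1L }
  }
  period_seq(all_periods[keep], all_amps[keep], unvoiced = FALSE,
             peak_times = all_times[keep], segment = all_seg[keep])
}

# Height of a waveform peak near fractional index `pos`, by windowed-sinc
# (band-limited) interpolation on a fine grid spanning +-1 sample. A
# 3-point parabola is too blunt for pulses only a few samples wide: its
# error varies with the sub-sample offset and reads as spurious shimmer.
sinc_peak_height <- function(x, pos, half = 16L) {
  k <- round(pos)
  if (k - half < 1L || k + half > length(x)) return(abs(x[min(max(k, 1L), length(x))]))
  n <- (k - half):(k + half)
  seg <- x[n]
  taper <- 0.5 + 0.5 * cos(pi * (n - k) / (half + 1))
  tt <- seq(k - 1, k + 1, by = 0.125)
  vals <- vapply(tt, function(t) sum(seg * taper * sinc(t - n)), numeric(1))
  j <- which.max(abs(vals))
  if (j > 1L && j < length(vals)) {
    abs(parabolic_peak(abs(vals[j - 1L]), abs(vals[j]),
                       abs(vals[j + 1L]))$value)
  } else abs(vals[j])
}

# Walk outward from an anchor peak, locating one positive waveform peak
# per expected cycle; positions refined by parabolic interpolation
# (fractional sample indices).
walk_peaks <- function(x, fs, anchor, per_of, i0, i1) {
  refine <- function(i) {
    if (i <= 1L || i >= length(x)) return(as.numeric(i))
    i + parabolic_peak(x[i - 1L], x[i], x[i + 1L])$offset
  }
  peaks <- refine(anchor)
  # forward
  cur <- anchor
  repeat {
    p <- per_of(cur / fs) * fs
    lo <- round(cur + 0.7 * p); hi <- round(cur + 1.35 * p)
    if (hi > i1) break
    w <- lo:hi
    nxt <- w[which.max(x[w])]
    if (x[nxt] <= 0) break
    peaks <- c(peaks, refine(nxt))
    cur <- nxt
  }
  # backward
  cur <- anchor
  repeat {
    p <- per_of(cur / fs) * fs
    lo <- round(cur - 1.35 * p); hi <- round(cur - 0.7 * p)
    if (lo < i0) break
    w <- lo:hi
    prv <- w[which.max(x[w])]
    if (x[prv] <= 0) break
    peaks <- c(refine(prv), peaks)
    cur <- prv
  }
  sort(peaks)
}
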