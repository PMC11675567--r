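#' Waveform container
#'
#' A `voice_wave` is a lightweight container for mono sampled audio:
#' a numeric vector of amplitudes in `[-1, 1]` plus its sampling rate.
#'
#' @param samples Numeric vector of amplitudes; must lie in `[-1, 1]`.
#' @param sample_rate_hz Sampling rate in samples per second.
#' @return An object of class `voice_wave` with fields `samples` and
#'   `sample_rate_hz`.
#' @export
waveform <- function(samples, sample_rate_hz) {
  samples <- as.numeric(samples)
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      sample_rate_hz <= 0) {
    stop("`sample_rate_hz` must be a single positive number", call. = FALSE)
  }
  if (length(samples) && max(abs(samples)) > 1 + 1e-9) {
    stop("waveform samples must lie in [-1, 1]", call. = FALSE)
  }
  structure(list(samples = samples, sample_rate_hz = sample_rate_hz),
            class = "voice_wave")
}

#' @export
print.voice_wave <- function(x, ...) {
  cat(sprintf("<voice_wave: %d samples @ %g Hz (%.3f s)>\n",
              length(x$samples), x$sample_rate_hz,
              length(x$samples) / x$sample_rate_hz))
  invisible(x)
}

#' @export
length.voice_wave <- function(x) length(x$samples)

wave_duration <- function(wave) length(wave$samples) / wave$sample_rate_hz

as_waveform <- function(x) {
  if (inherits(x, "voice_wave")) return(x)
  stop("expected a `voice_wave` object", call. = FALSE)
}

# ---- RIFF/WAVE PCM I/O -------------------------------------------------
# Hand-rolled because no audio package ships in this environment. Mono
# integer PCM only, which is all the pipeline produces (16-bit) or accepts
# (16/24-bit).

#' Write a waveform to a WAV file
#'
#' Writes mono 16-bit integer PCM (RIFF/WAVE), no dither.
#'
#' @param wave A [waveform()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path) {
  wave <- as_waveform(wave)
  x <- pmin(1, pmax(-1, wave$samples))
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(pcm) * 2L
  fs <- as.integer(round(wave$sample_rate_hz))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")       # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")        # PCM
  writeBin(1L, con, size = 2, endian = "little")        # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * 2L, con, size = 4, endian = "little")   # byte rate
  writeBin(2L, con, size = 2, endian = "little")        # block align
  writeBin(16L, con, size = 2, endian = "little")       # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono PCM WAV file
#'
#' Supports 16- and 24-bit integer PCM, mono. Chunks other than `fmt ` and
#' `data` are skipped.
#'
#' @param path Path to a `.wav` file.
#' @return A [waveform()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wavetag <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wavetag, "WAVE")) {
    stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  }
  fmt <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) stop("no data chunk in ", path)
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      audio_format <- readBin(con, "integer", 1, size = 2, endian = "little")
      n_channels <- readBin(con, "integer", 1, size = 2, endian = "little")
      rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (sz > 16) readBin(con, "raw", sz - 16L)
      if (audio_format != 1L) stop("only integer PCM WAV supported")
      if (n_channels != 1L) stop("only mono WAV supported")
      if (!bits %in% c(16L, 24L)) stop("only 16/24-bit PCM supported")
      fmt <- list(rate = rate, bits = bits)
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("data chunk before fmt chunk in ", path)
      if (fmt$bits == 16L) {
        pcm <- readBin(con, "integer", sz / 2L, size = 2, signed = TRUE,
                       endian = "little")
        x <- pcm / 32767  # symmetric with the writer's scaling
      } else {
        raw <- readBin(con, "raw", sz)
        b <- matrix(as.integer(raw), nrow = 3L)
        v <- b[1, ] + 256L * b[2, ] + 65536L * b[3, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
        x <- v / 8388607
      }
      return(waveform(pmin(1, pmax(-1, x)), fmt$rate))
    } else {
      readBin(con, "raw", sz + (sz %% 2L))  # chunks are word-aligned
    }
  }
}

# ---- basic DSP helpers -------------------------------------------------

# Slice a signal into frames (columns), Hann-windowed on request.
frame_signal <- function(x, frame_len, hop) {
  n <- length(x)
  if (n < frame_len) return(NULL)
  starts <- seq(1L, n - frame_len + 1L, by = hop)
  idx <- outer(seq_len(frame_len) - 1L, starts, `+`)
  matrix(x[idx], nrow = frame_len)
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))

# Normalized autocorrelation of a windowed frame, divided by the window's
# own autocorrelation (Boersma's correction) so a perfectly periodic frame
# scores ~1 at its period lag.
normalized_acf <- function(frame, window, window_acf, max_lag) {
  xw <- (frame - mean(frame)) * window
  nfft <- 2L * length(xw)
  sp <- stats::fft(c(xw, numeric(nfft - length(xw))))
  ac <- Re(stats::fft(sp * Conj(sp), inverse = TRUE))[seq_len(max_lag + 1L)]
  if (ac[1] <= 0) return(numeric(max_lag + 1L))
  r <- ac / ac[1]
  r / window_acf[seq_len(max_lag + 1L)]
}

window_acf_table <- function(window, max_lag) {
  nfft <- 2L * length(window)
  sp <- stats::fft(c(window, numeric(nfft - length(window))))
  ac <- Re(stats::fft(sp * Conj(sp), inverse = TRUE))[seq_len(max_lag + 1L)]
  ac / ac[1]
}

# Parabolic (three-point) interpolation around a discrete peak.
# Returns list(offset in [-0.5, 0.5], value at vertex).
parabolic_peak <- function(ym1, y0, yp1) {
  denom <- ym1 - 2 * y0 + yp1
  if (!is.finite(denom) || abs(denom) < 1e-30) {
    return(list(offset = 0, value = y0))
  }
  off <- 0.5 * (ym1 - yp1) / denom
  off <- max(-0.5, min(0.5, off))
  list(offset = off, value = y0 - 0.25 * (ym1 - yp1) * off)
}

# Windowed-sinc FIR low-pass, used before downsampling.
fir_lowpass <- function(cutoff_norm, n_taps = 101L) {
  m <- n_taps - 1L
  k <- seq(0L, m) - m / 2
  h <- 2 * cutoff_norm * sinc(2 * cutoff_norm * k)
  h * hann_window(n_taps)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

fir_filter <- function(x, h) {
  n <- length(x); m <- length(h)
  nfft <- stats::nextn(n + m - 1L, 2)
  y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - n))) *
                     stats::fft(c(h, numeric(nfft - m))), inverse = TRUE)) / nfft
  # compensate the FIR group delay so the output is time-aligned
  delay <- (m - 1L) %/% 2L
  y[seq.int(delay + 1L, delay + n)]
}

# Resample by low-pass filtering then linear interpolation; adequate for
# the 44.1 kHz -> 10 kHz formant path.
resample_wave <- function(wave, new_rate) {
  wave <- as_waveform(wave)
  if (abs(new_rate - wave$sample_rate_hz) < 1e-9) return(wave)
  x <- wave$samples
  if (new_rate < wave$sample_rate_hz) {
    cutoff <- 0.45 * new_rate / wave$sample_rate_hz
    x <- fir_filter(x, fir_lowpass(cutoff))
  }
  n_new <- max(1L, round(length(x) * new_rate / wave$sample_rate_hz))
  t_old <- (seq_along(x) - 1) / wave$sample_rate_hz
  t_new <- (seq_len(n_new) - 1) / new_rate
  y <- stats::approx(t_old, x, xout = t_new, rule = 2)$y
  waveform(pmin(1, pmax(-1, y)), new_rate)
}

# Second-order resonator (two-pole) filter bank applied in cascade.
# freqs/bws in Hz. Each section is normalized to unit gain at the
# resonance frequency.
resonator_cascade <- function(x, freqs, bws, fs) {
  for (i in seq_along(freqs)) {
    f <- freqs[i]; bw <- bws[i]
    r <- exp(-pi * bw / fs)
    theta <- 2 * pi * f / fs
    a1 <- 2 * r * cos(theta)
    a2 <- -r^2
    # gain normalization at DC-ish scale: use peak gain at resonance
    b0 <- (1 - r) * sqrt(1 - 2 * r * cos(2 * theta) + r^2)
    x <- stats::filter(b0 * x, c(a1, a2), method = "recursive")
    x <- as.numeric(x)
  }
  x
}

rms <- function(x) sqrt(mean(x^2))
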