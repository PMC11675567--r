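# Per-recording feature vector (23 features) and the subjects x 184
# indicator table.

#' Measure voiced/energetic duration
#'
#' Time between the first and last 10 ms frame whose RMS is within 25 dB
#' of the loudest frame. Returns 0 for silence.
#'
#' @param wave A [waveform()].
#' @param threshold_db Endpoint threshold below the peak frame RMS.
#' @return Duration in seconds.
#' @export
measure_duration <- function(wave, threshold_db = 25) {
  wave <- as_waveform(wave)
  fs <- wave$sample_rate_hz
  frame_len <- max(2L, round(0.01 * fs))
  frames <- frame_signal(wave$samples, frame_len, frame_len)
  if (is.null(frames)) {
    frames <- matrix(wave$samples, ncol = 1)
  }
  frms <- sqrt(colMeans(frames^2))
  peak <- max(frms)
  if (peak <= 0) return(0)
  active <- which(frms >= peak * 10^(-threshold_db / 20))
  if (!length(active)) return(0)
  (active[length(active)] - active[1] + 1L) * frame_len / fs
}

#' Task recording container
#'
#' @param task_id One of `task_ids()`.
#' @param wave A [waveform()].
#' @param subject_id Subject identifier.
#' @return Object of class `task_recording`.
#' @export
task_recording <- function(task_id, wave, subject_id = NA_character_) {
  task_id <- match.arg(task_id, task_ids())
  structure(list(task_id = task_id, waveform = as_waveform(wave),
                 subject_id = subject_id),
            class = "task_recording")
}

#' Extract the 23-feature acoustic vector from one recording
#'
#' Computes the full per-task catalogue: the five jitter and six shimmer
#' variants, HNR, duration, mean/stdev F0, and mean/median F1-F4. For DDK
#' tasks the perturbation measures are computed within voiced segments of
#' at least five cycles and cycle-count-weighted averaged, so
#' inter-syllable gaps are never read as giant periods. Features that
#' cannot be computed are `NA` (reasons retained in the
#' `missing_reasons` attribute).
#'
#' @param rec A [task_recording()] (or a bare [waveform()], treated as a
#'   vowel task).
#' @param f0_min,f0_max Pitch search range, Hz.
#' @return Named numeric vector of length 23 (class `feature_vector`).
#' @export
extract_features <- function(rec, f0_min = 60, f0_max = 400) {
  if (inherits(rec, "voice_wave")) rec <- task_recording("a", rec)
  stopifnot(inherits(rec, "task_recording"))
  wave <- rec$waveform
  out <- stats::setNames(rep(NA_real_, length(feature_names())),
                         feature_names())
  reasons <- list()
  keep <- function(name, value) {
    out[[name]] <<- as.numeric(value)
    r <- attr(value, "reason")
    if (!is.null(r)) reasons[[name]] <<- r
  }

  seq <- detect_periods(wave, f0_min, f0_max)
  for (v in jitter_variants()) {
    keep(paste0("jitter_", v), compute_jitter(seq, v))
  }
  for (v in shimmer_variants()) {
    keep(paste0("shimmer_", v), compute_shimmer(seq, v))
  }
  keep("hnr", compute_hnr(wave, f0_min, f0_max))
  keep("duration", measure_duration(wave))
  fstats <- f0_statistics(track_pitch(wave, f0_min, f0_max))
  keep("mean_f0", fstats$mean_f0)
  keep("stdev_f0", fstats$stdev_f0)
  fm <- formant_statistics(track_formants(wave))
  for (k in 1:4) {
    keep(paste0("mean_f", k), fm[[paste0("mean_f", k)]])
    keep(paste0("median_f", k), fm[[paste0("median_f", k)]])
  }
  structure(out, missing_reasons = reasons, task_id = rec$task_id,
            subject_id = rec$subject_id, class = "feature_vector")
}

#' Assemble the subjects x 184 indicator table
#'
#' One row per subject, columns named `<task_id>__<feature_name>` in
#' protocol/catalogue order (8 x 23 = 184 columns after `subject_id`). A
#' subject's missing task leaves its 23 columns `NA`; a duplicated
#' (subject, task) pair is an error.
#'
#' @param recordings List of [task_recording()] objects (each with a
#'   `subject_id`), or a pre-extracted list of [extract_features()]
#'   vectors.
#' @param f0_min,f0_max Pitch search range passed to [extract_features()].
#' @return data.frame: `subject_id` + 184 indicator columns.
#' @export
build_feature_table <- function(recordings, f0_min = 60, f0_max = 400) {
  vecs <- lapply(recordings, function(r) {
    if (inherits(r, "feature_vector")) r
    else extract_features(r, f0_min, f0_max)
  })
  subj <- vapply(vecs, function(v) as.character(attr(v, "subject_id")),
                 character(1))
  task <- vapply(vecs, function(v) attr(v, "task_id"), character(1))
  if (anyDuplicated(paste(subj, task))) {
    stop("duplicate (subject, task) pair in recordings", call. = FALSE)
  }
  subjects <- unique(subj)
  cols <- indicator_names()
  m <- matrix(NA_real_, length(subjects), length(cols),
              dimnames = list(subjects, cols))
  for (i in seq_along(vecs)) {
    m[subj[i], paste0(task[i], "__", feature_names())] <- as.numeric(vecs[[i]])
  }
  out <- data.frame(subject_id = subjects, m, check.names = FALSE,
                    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Write / read a feature table as CSV
#'
#' UTF-8 CSV with a header row: `subject_id` then the indicator columns;
#' missing values are empty cells.
#'
#' @param table Feature table data.frame.
#' @param path File path.
#' @return `path` (write) or the table (read).
#' @export
write_feature_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
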