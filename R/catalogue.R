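# The task and feature catalogue: 8 speech tasks x 23 acoustic features
# = 184 indicators. "avg_formant" (mean of the four per-formant means) is
# a derived summary returned by formant_statistics() but is not a distinct
# indicator column, keeping the catalogue at exactly 23.

#' @rdname extract_features
#' @export
task_ids <- function() {
  c("a", "i", "u", "a_prolonged", "puh", "tuh", "kuh", "puhtuhkuh")
}

ddk_task_ids <- function() c("puh", "tuh", "kuh", "puhtuhkuh")

#' @rdname extract_features
#' @export
feature_names <- function() {
  c("jitter_local", "jitter_absolute", "jitter_rap", "jitter_ppq5",
    "jitter_ddp",
    "shimmer_local", "shimmer_local_db", "shimmer_apq3", "shimmer_apq5",
    "shimmer_apq11", "shimmer_dda",
    "hnr", "duration", "mean_f0", "stdev_f0",
    "mean_f1", "mean_f2", "mean_f3", "mean_f4",
    "median_f1", "median_f2", "median_f3", "median_f4")
}

#' Indicator (column) names of the full feature table
#'
#' Columns are named `<task_id>__<feature_name>`, tasks in protocol order,
#' features in catalogue order.
#'
#' @param n Optionally truncate to the first `n` names (used by the cohort
#'   simulator when a reduced table is requested).
#' @return Character vector of indicator names.
#' @export
indicator_names <- function(n = NULL) {
  nm <- as.vector(t(outer(task_ids(), feature_names(),
                          function(a, b) paste0(a, "__", b))))
  if (!is.null(n)) {
    if (n > length(nm)) {
      nm <- c(nm, sprintf("extra_%03d", seq_len(n - length(nm))))
    } else {
      nm <- nm[seq_len(n)]
    }
  }
  nm
}
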