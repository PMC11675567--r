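# Jitter (frequency perturbation) and shimmer (amplitude perturbation)
# families, computed on a PeriodSequence. Relative variants are percent of
# the mean period/amplitude; absolute jitter is in seconds; local-dB
# shimmer in dB. A value that cannot be computed is returned as NA with a
# "reason" attribute rather than an error.

missing_value <- function(reason) structure(NA_real_, reason = reason)

#' @rdname compute_jitter
#' @export
jitter_variants <- function() c("local", "absolute", "rap", "ppq5", "ddp")

#' @rdname compute_shimmer
#' @export
shimmer_variants <- function() {
  c("local", "local_db", "apq3", "apq5", "apq11", "dda")
}

min_cycles <- function(variant) {
  switch(variant, local = 2L, absolute = 2L, local_db = 2L,
         rap = 3L, apq3 = 3L, ddp = 3L, dda = 3L,
         ppq5 = 5L, apq5 = 5L, apq11 = 11L)
}

# mean |x_i - K-point moving average centred on i| (K odd)
perturbation_quotient <- function(x, K) {
  h <- (K - 1L) %/% 2L
  n <- length(x)
  idx <- (h + 1L):(n - h)
  ma <- vapply(idx, function(i) mean(x[(i - h):(i + h)]), numeric(1))
  mean(abs(x[idx] - ma))
}

# If the perturbation statistics are to be computed within voiced segments
# (DDK recordings), split, compute per segment with >= min_n cycles, and
# average weighted by cycle count.
segmented_stat <- function(seq, min_n, fun) {
  if (is.null(seq$segment) || length(unique(seq$segment)) == 1L) {
    if (seq$n < min_n) return(missing_value("too_few_cycles"))
    return(fun(seq$periods, seq$amplitudes))
  }
  vals <- c(); wts <- c()
  for (s in unique(seq$segment)) {
    sel <- seq$segment == s
    if (sum(sel) < max(min_n, 5L)) next
    v <- fun(seq$periods[sel], seq$amplitudes[sel])
    if (is.finite(v)) { vals <- c(vals, v); wts <- c(wts, sum(sel)) }
  }
  if (!length(vals)) return(missing_value("too_few_cycles"))
  sum(vals * wts) / sum(wts)
}

#' Jitter (period perturbation) measures
#'
#' `local` is the mean absolute difference between consecutive cycle
#' durations divided by the mean duration, in percent; `absolute` is the
#' un-normalized mean difference in seconds; `rap` compares each period
#' with the 3-point moving average, `ppq5` with the 5-point moving
#' average; `ddp` is the mean absolute difference of consecutive
#' differences. `ddp = 3 * rap` identically.
#'
#' @param seq A [period_seq()].
#' @param variant One of `jitter_variants()`.
#' @return Jitter value (percent; seconds for `absolute`), or `NA` with a
#'   `reason` attribute when fewer cycles than the variant needs are
#'   available.
#' @export
compute_jitter <- function(seq, variant = c("local", "absolute", "rap",
                                            "ppq5", "ddp")) {
  variant <- match.arg(variant)
  stopifnot(inherits(seq, "period_seq"))
  if (seq$unvoiced) return(missing_value("unvoiced"))
  segmented_stat(seq, min_cycles(variant), function(p, a) {
    pbar <- mean(p)
    switch(variant,
      local = mean(abs(diff(p))) / pbar * 100,
      absolute = mean(abs(diff(p))),
      rap = perturbation_quotient(p, 3L) / pbar * 100,
      ppq5 = perturbation_quotient(p, 5L) / pbar * 100,
      ddp = mean(abs(diff(diff(p)))) / pbar * 100)
  })
}

#' Shimmer (amplitude perturbation) measures
#'
#' `local` is the mean absolute difference between consecutive cycle peak
#' amplitudes divided by the mean amplitude, percent; `local_db` the mean
#' absolute dB difference; `apq3`/`apq5`/`apq11` compare each amplitude
#' with the K-point moving average; `dda` is the mean absolute difference
#' of consecutive differences. `dda = 3 * apq3` identically.
#'
#' @param seq A [period_seq()].
#' @param variant One of `shimmer_variants()`.
#' @return Shimmer value (percent; dB for `local_db`), or `NA` with a
#'   `reason` attribute (too few cycles, or a zero amplitude for
#'   `local_db`).
#' @export
compute_shimmer <- function(seq, variant = c("local", "local_db", "apq3",
                                             "apq5", "apq11", "dda")) {
  variant <- match.arg(variant)
  stopifnot(inherits(seq, "period_seq"))
  if (seq$unvoiced) return(missing_value("unvoiced"))
  if (variant == "local_db" && any(seq$amplitudes == 0)) {
    return(missing_value("zero_amplitude"))
  }
  segmented_stat(seq, min_cycles(variant), function(p, a) {
    abar <- mean(a)
    switch(variant,
      local = mean(abs(diff(a))) / abar * 100,
      local_db = mean(abs(20 * log10(a[-1] / a[-length(a)]))),
      apq3 = perturbation_quotient(a, 3L) / abar * 100,
      apq5 = perturbation_quotient(a, 5L) / abar * 100,
      apq11 = perturbation_quotient(a, 11L) / abar * 100,
      dda = mean(abs(diff(diff(a)))) / abar * 100)
  })
}
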