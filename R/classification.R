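# The three binary screening tasks, the prevalence baseline for PR-AUC,
# stratified splitting, and the evaluation metric set.

#' Task counts
#'
#' @param n_positive Number of positive (impaired) samples.
#' @param n_total Total number of samples.
#' @return Object of class `task_counts`.
#' @export
task_counts <- function(n_positive, n_total) {
  stopifnot(n_positive > 0, n_positive < n_total)
  structure(list(n_positive = as.integer(n_positive),
                 n_total = as.integer(n_total)),
            class = "task_counts")
}

#' Baseline PR-AUC (class prevalence)
#'
#' The chance level of the precision-recall AUC equals the positive-class
#' prevalence: number of positive samples over all samples.
#'
#' @param counts A [task_counts()].
#' @param digits Decimal places for the reported value (default 3).
#' @return Prevalence in (0, 1), rounded to `digits`.
#' @export
baseline_pr_auc <- function(counts, digits = 3) {
  stopifnot(inherits(counts, "task_counts"))
  round(counts$n_positive / counts$n_total, digits)
}

#' Build the three binary classification tasks from a roster
#'
#' Positive class is the impaired side: severe vs normal, mild vs normal,
#' and combined (severe + mild) vs normal. Tasks whose positive or
#' negative class is empty are skipped with a warning.
#'
#' @param roster data.frame with a `group` column (severe/mild/normal) or
#'   a `kmmse` column.
#' @return Named list of tasks; each has `name`, `positive_groups`,
#'   `negative_groups`, `counts` ([task_counts()]), and `subject_index`
#'   (rows of the roster in the task) plus `labels` (1 = impaired).
#' @export
make_tasks <- function(roster) {
  if (is.null(roster$group)) roster$group <- assign_group(roster$kmmse)
  g <- factor(roster$group, levels = group_levels)
  defs <- list(
    severe_vs_normal = list(pos = "severe", neg = "normal"),
    mild_vs_normal = list(pos = "mild", neg = "normal"),
    combined_vs_normal = list(pos = c("severe", "mild"), neg = "normal"))
  out <- list()
  for (nm in names(defs)) {
    d <- defs[[nm]]
    idx <- which(g %in% c(d$pos, d$neg))
    labels <- as.integer(g[idx] %in% d$pos)
    if (!sum(labels) || all(labels == 1L)) {
      warning("task ", nm, " skipped: empty class", call. = FALSE)
      next
    }
    out[[nm]] <- list(name = nm, positive_groups = d$pos,
                      negative_groups = d$neg,
                      counts = task_counts(sum(labels), length(labels)),
                      subject_index = idx, labels = labels)
  }
  out
}

#' Split configuration
#'
#' @param test_fraction Held-out fraction (default 0.2, the 8:2 split).
#' @param n_folds Cross-validation folds (default 5).
#' @param seed Integer seed.
#' @return Object of class `split_config`.
#' @export
split_config <- function(test_fraction = 0.2, n_folds = 5, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1, n_folds >= 2)
  structure(list(test_fraction = test_fraction, n_folds = as.integer(n_folds),
                 seed = as.integer(seed), stratified = TRUE),
            class = "split_config")
}

#' Stratified train/test split
#'
#' Per class, `floor(n_class * test_fraction)` samples go to the test set
#' and the class with the largest fractional remainder absorbs the
#' leftover needed to reach `round(n * test_fraction)` (floor + remainder
#' assignment). Deterministic under a fixed seed.
#'
#' @param labels 0/1 integer vector.
#' @param config A [split_config()].
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, config = split_config()) {
  stopifnot(inherits(config, "split_config"))
  if (min(table(labels)) < 2L) {
    stop("stratification requires >= 2 samples per class", call. = FALSE)
  }
  withr_seed(config$seed, {
    n <- length(labels)
    target_total <- round(n * config$test_fraction)
    classes <- sort(unique(labels))
    per_class <- vapply(classes, function(cl) sum(labels == cl), numeric(1))
    base <- floor(per_class * config$test_fraction)
    rem <- per_class * config$test_fraction - base
    short <- target_total - sum(base)
    if (short > 0) {
      add <- order(rem, decreasing = TRUE)[seq_len(short)]
      base[add] <- base[add] + 1L
    }
    test <- integer(0)
    for (k in seq_along(classes)) {
      idx <- which(labels == classes[k])
      test <- c(test, sample(idx, base[k]))
    }
    test <- sort(test)
    list(train = setdiff(seq_len(n), test), test = test)
  })
}

# Stratified fold assignment for CV (1..n_folds per sample).
stratified_folds <- function(labels, n_folds, seed) {
  withr_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    fold
  })
}

# ---- metrics -----------------------------------------------------------

#' Precision-recall AUC (average precision)
#'
#' Step integration of the precision-recall curve: the sum over distinct
#' score thresholds of precision times the recall increment. Trapezoidal
#' interpolation is deliberately not used (it overestimates PR curves).
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels 0/1 labels; both classes must be present.
#' @return Average precision in `[0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (!any(labels == 1) || !any(labels == 0)) {
    stop("PR-AUC needs both classes present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  # evaluate at the last index of each tied score block
  last <- which(c(s[-1] != s[-length(s)], TRUE))
  prec <- tp[last] / (tp[last] + fp[last])
  rec <- tp[last] / sum(y)
  sum(prec * diff(c(0, rec)))
}

#' ROC AUC by the rank statistic
#'
#' Mann-Whitney form with tie correction (ties count one half).
#'
#' @inheritParams pr_auc
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  stopifnot(n1 > 0, n0 > 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a score vector against the Table-5 metric set
#'
#' PR-AUC (average precision), ROC AUC, and threshold metrics (accuracy,
#' F1, precision, recall) at score 0.5, plus the prevalence baseline and
#' the relative improvement over it.
#'
#' @param scores Predicted probabilities for the positive class.
#' @param labels 0/1 labels (both classes present).
#' @param counts [task_counts()] of the task; defaults to the counts of
#'   `labels` itself.
#' @return List of class `eval_report`: `pr_auc`, `auc`, `accuracy`, `f1`,
#'   `precision`, `recall`, `baseline_pr_auc`, `improvement_pct`.
#' @export
evaluate_scores <- function(scores, labels, counts = NULL) {
  if (is.null(counts)) counts <- task_counts(sum(labels), length(labels))
  ap <- pr_auc(scores, labels)
  auc <- roc_auc(scores, labels)
  pred <- as.integer(scores >= 0.5)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  base <- baseline_pr_auc(counts)
  structure(list(pr_auc = ap, auc = auc,
                 accuracy = mean(pred == labels), f1 = f1,
                 precision = precision, recall = recall,
                 baseline_pr_auc = base,
                 improvement_pct = (ap - base) / base * 100),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("PR-AUC %.3f (baseline %.3f, %+.0f%%) | AUC %.3f | ",
                     "acc %.3f | F1 %.3f | P %.3f | R %.3f\n"),
              x$pr_auc, x$baseline_pr_auc, x$improvement_pct, x$auc,
              x$accuracy, x$f1, x$precision, x$recall))
  invisible(x)
}

#' Improvement over the prevalence baseline
#'
#' Relative gain of a PR-AUC over the baseline, in percent.
#'
#' @param pr_auc Achieved PR-AUC.
#' @param baseline Baseline PR-AUC (prevalence).
#' @return `(pr_auc - baseline) / baseline * 100`.
#' @export
improvement_pct <- function(pr_auc, baseline) {
  (pr_auc - baseline) / baseline * 100
}
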