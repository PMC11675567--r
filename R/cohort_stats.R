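# Cognitive-status grouping and the demographic comparison battery:
# Kruskal-Wallis across the three groups, chi-square for sex, Shapiro-Wilk
# and Levene checks motivating the nonparametric choice, and
# Bonferroni-corrected pairwise Mann-Whitney post hocs.

#' Assign a cognitive-status group from a K-MMSE score
#'
#' Cut-offs: 0-19 severe, 20-23 mild, 24-30 normal.
#'
#' @param kmmse Integer score(s) in `[0, 30]`.
#' @return Factor with levels severe/mild/normal.
#' @export
assign_group <- function(kmmse) {
  kmmse <- as.integer(kmmse)
  if (any(is.na(kmmse)) || any(kmmse < 0L | kmmse > 30L)) {
    stop("K-MMSE scores must be integers in [0, 30]", call. = FALSE)
  }
  factor(ifelse(kmmse <= 19L, "severe",
                ifelse(kmmse <= 23L, "mild", "normal")),
         levels = group_levels)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H with a chi-square reference on k-1 degrees of freedom.
#'
#' @param groups List of >= 2 non-empty numeric vectors.
#' @return List: `statistic` (H), `p_value`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L || any(!lengths(groups))) {
    stop("need >= 2 non-empty groups", call. = FALSE)
  }
  if (length(unique(unlist(groups))) == 1L) {
    # all observations tied: H = 0 by convention (kruskal.test gives 0/0)
    return(list(statistic = 0, p_value = 1, df = length(groups) - 1L))
  }
  kt <- stats::kruskal.test(groups)
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter))
}

#' Pearson chi-square test of independence
#'
#' No continuity correction; df = (r-1)(c-1).
#'
#' @param table r x c matrix of counts (>= 2x2, no zero margins).
#' @return List: `statistic`, `p_value`, `df`.
#' @export
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  stopifnot(nrow(table) >= 2L, ncol(table) >= 2L, all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero row/column margin", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       df = unname(ct$parameter))
}

#' Bonferroni-corrected pairwise Mann-Whitney comparisons
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) tests for every pair of
#' groups; each p-value is multiplied by the number of comparisons and
#' capped at 1.
#'
#' @param groups Named list of numeric vectors.
#' @return data.frame: `group1`, `group2`, `p_raw`, `p_adjusted`,
#'   `testable` (FALSE when a group has < 2 observations).
#' @export
posthoc_pairwise <- function(groups) {
  stopifnot(length(groups) >= 2L)
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_along(groups))
  pairs <- utils::combn(seq_along(groups), 2)
  m <- ncol(pairs)
  res <- lapply(seq_len(m), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    if (length(groups[[i]]) < 2L || length(groups[[j]]) < 2L) {
      return(data.frame(group1 = nm[i], group2 = nm[j], p_raw = NA_real_,
                        p_adjusted = NA_real_, testable = FALSE))
    }
    p <- suppressWarnings(
      stats::wilcox.test(groups[[i]], groups[[j]], exact = FALSE)$p.value)
    data.frame(group1 = nm[i], group2 = nm[j], p_raw = p,
               p_adjusted = min(1, m * p), testable = TRUE)
  })
  do.call(rbind, res)
}

#' Normality and homogeneity-of-variance checks
#'
#' Shapiro-Wilk per group and Levene's test (classic, mean-centred
#' absolute deviations compared by one-way ANOVA) across groups. Reported
#' to justify the nonparametric test choice.
#'
#' @param groups Named list of numeric vectors, each of size >= 3.
#' @return List: `shapiro_p` (named per group), `levene_p`.
#' @export
normality_and_variance_checks <- function(groups) {
  stopifnot(all(lengths(groups) >= 3L))
  shapiro_p <- vapply(groups, function(x) stats::shapiro.test(x)$p.value,
                      numeric(1))
  z <- unlist(lapply(groups, function(x) abs(x - mean(x))))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  levene_p <- stats::anova(stats::lm(z ~ g))[["Pr(>F)"]][1]
  list(shapiro_p = shapiro_p, levene_p = levene_p)
}

#' Demographic comparison report
#'
#' Mirrors the study's demographic tables: Kruskal-Wallis for age and
#' education across the three groups, chi-square for the sex-by-group
#' contingency table, assumption checks, and Bonferroni-corrected
#' pairwise post hocs.
#'
#' @param roster data.frame with columns `age`, `education`, `sex`,
#'   `group` (or `kmmse`, from which groups are assigned).
#' @return List of class `demographic_report` with elements `omnibus`
#'   (data.frame), `sex_table`, `sex_test`, `posthoc` (named list of
#'   data.frames), `assumptions`.
#' @export
demographic_report <- function(roster) {
  if (is.null(roster$group)) roster$group <- assign_group(roster$kmmse)
  roster$group <- factor(roster$group, levels = group_levels)
  present <- levels(droplevels(roster$group))
  split_var <- function(v) split(roster[[v]], droplevels(roster$group))
  omnibus <- do.call(rbind, lapply(c("age", "education"), function(v) {
    kw <- kruskal_wallis(split_var(v))
    data.frame(variable = v, test = "Kruskal-Wallis",
               statistic = kw$statistic, df = kw$df, p_value = kw$p_value)
  }))
  sex_table <- table(roster$group, roster$sex)[present, , drop = FALSE]
  sex_test <- chi_square_independence(sex_table)
  posthoc <- lapply(stats::setNames(c("age", "education"),
                                    c("age", "education")),
                    function(v) posthoc_pairwise(split_var(v)))
  assumptions <- lapply(stats::setNames(c("age", "education"),
                                        c("age", "education")),
                        function(v) normality_and_variance_checks(split_var(v)))
  structure(list(omnibus = omnibus, sex_table = sex_table,
                 sex_test = sex_test, posthoc = posthoc,
                 assumptions = assumptions),
            class = "demographic_report")
}

#' @export
print.demographic_report <- function(x, ...) {
  cat("Group comparisons of demographic characteristics\n")
  print(x$omnibus, row.names = FALSE)
  cat(sprintf("Sex: chi-square = %.2f (df %d), p = %.3f\n",
              x$sex_test$statistic, x$sex_test$df, x$sex_test$p_value))
  for (v in names(x$posthoc)) {
    cat("Post hoc (Bonferroni), ", v, ":\n", sep = "")
    print(x$posthoc[[v]], row.names = FALSE)
  }
  invisible(x)
}
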