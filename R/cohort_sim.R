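# Synthetic cohort generator: roster demographics follow the study's
# printed per-group distributions; indicator rows are group mean shifts
# plus equicorrelated Gaussian noise.

group_levels <- c("severe", "mild", "normal")

kmmse_ranges <- list(severe = c(0L, 19L), mild = c(20L, 23L),
                     normal = c(24L, 30L))

# per-group demographic distributions (mean, sd, min, max); male counts
cohort_demographics <- list(
  severe = list(age = c(72.44, 8.57, 46, 87), edu = c(7.10, 4.49, 0, 16),
                p_male = 32 / 72),
  mild   = list(age = c(71.11, 8.36, 48, 84), edu = c(8.24, 4.05, 0, 16),
                p_male = 31 / 54),
  normal = list(age = c(64.80, 11.30, 30, 85), edu = c(10.93, 4.13, 0, 16),
                p_male = 43 / 97)
)

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lo & draw <= hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Generate a synthetic study cohort
#'
#' Draws a roster of subjects (K-MMSE score uniform inside each group's
#' cut-off range, age/education from truncated normals matched to the
#' per-group summary statistics, sex from the per-group proportions) and an
#' indicator table whose rows are per-group mean shifts (from
#' `effect_map`, in within-group SD units) plus equicorrelated standard
#' Gaussian noise.
#'
#' @param params A [cohort_params()].
#' @return A list with `features` (data.frame: `subject_id` +
#'   `params$n_features` indicator columns) and `roster` (data.frame:
#'   `subject_id`, `age`, `education`, `sex`, `kmmse`, `group`).
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  withr_seed(params$seed, {
    sizes <- params$group_sizes
    n <- sum(sizes)
    group <- factor(rep(group_levels, times = sizes), levels = group_levels)
    subject_id <- sprintf("S%03d", seq_len(n))
    kmmse <- integer(n); age <- numeric(n); edu <- numeric(n)
    sex <- character(n)
    for (g in group_levels) {
      idx <- which(group == g)
      if (!length(idx)) next
      d <- cohort_demographics[[g]]
      r <- kmmse_ranges[[g]]
      kmmse[idx] <- sample(seq(r[1], r[2]), length(idx), replace = TRUE)
      age[idx] <- round(rnorm_trunc(length(idx), d$age[1], d$age[2],
                                    d$age[3], d$age[4]), 1)
      edu[idx] <- round(rnorm_trunc(length(idx), d$edu[1], d$edu[2],
                                    d$edu[3], d$edu[4]))
      sex[idx] <- ifelse(stats::runif(length(idx)) < d$p_male,
                         "male", "female")
    }
    roster <- data.frame(subject_id = subject_id, age = age,
                         education = edu, sex = sex, kmmse = kmmse,
                         group = group, stringsAsFactors = FALSE)

    nm <- indicator_names(params$n_features)
    rho <- params$base_correlation
    z_common <- stats::rnorm(n)
    noise <- sqrt(rho) * matrix(z_common, n, params$n_features) +
      sqrt(1 - rho) * matrix(stats::rnorm(n * params$n_features), n)
    shifts <- matrix(0, n, params$n_features, dimnames = list(NULL, nm))
    for (feat in names(params$effect_map)) {
      ef <- params$effect_map[[feat]]
      for (g in intersect(names(ef), group_levels)) {
        shifts[group == g, feat] <- ef[[g]]
      }
    }
    features <- as.data.frame(shifts + noise)
    names(features) <- nm
    features <- cbind(subject_id = subject_id, features,
                      stringsAsFactors = FALSE)
    list(features = features, roster = roster)
  })
}
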