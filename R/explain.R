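# Shapley-value feature attribution with the interventional (marginal)
# value function: v(S) is the mean model score over a background sample
# with the features in S pinned to the explained instance. An exact
# enumeration oracle is provided up to 15 features; at scale, a seeded
# permutation-sampling estimator with Monte-Carlo standard errors.

#' Define a Shapley attribution problem
#'
#' @param predict_fn Function mapping a numeric matrix (rows = instances)
#'   to a numeric score vector.
#' @param background Background/reference matrix or data.frame (rows drawn
#'   from the training data; at most a few hundred).
#' @param feature_names Column names; taken from `background` by default.
#' @return Object of class `shapley_problem`.
#' @export
shapley_problem <- function(predict_fn, background,
                            feature_names = colnames(background)) {
  background <- as.matrix(background)
  stopifnot(is.function(predict_fn), nrow(background) >= 1)
  if (is.null(feature_names)) {
    feature_names <- paste0("x", seq_len(ncol(background)))
  }
  colnames(background) <- feature_names
  structure(list(predict_fn = predict_fn, background = background,
                 feature_names = feature_names,
                 base_value = mean(predict_fn(background))),
            class = "shapley_problem")
}

# v(S): mean prediction over background rows with features in S replaced
# by the instance's values.
coalition_value <- function(problem, instance, S) {
  B <- problem$background
  if (length(S)) B[, S] <- matrix(instance[S], nrow(B), length(S),
                                  byrow = TRUE)
  mean(problem$predict_fn(B))
}

#' Exact Shapley values by coalition enumeration
#'
#' Literal evaluation of the Shapley formula over all `2^N` coalitions;
#' the attribution of feature i is the weighted average of
#' `v(S + i) - v(S)` over subsets S not containing i, with weight
#' `|S|! (N-|S|-1)! / N!`. Refuses more than 15 features; use
#' [sampled_shapley()] beyond that.
#'
#' @param problem A [shapley_problem()].
#' @param instance Numeric vector (one row) to explain.
#' @return Named numeric vector of attributions; attributes `base_value`
#'   and `prediction` (their sum equals the prediction).
#' @export
exact_shapley <- function(problem, instance) {
  stopifnot(inherits(problem, "shapley_problem"))
  N <- length(problem$feature_names)
  if (N > 15L) {
    stop("exact enumeration is limited to 15 features; ",
         "use sampled_shapley()", call. = FALSE)
  }
  instance <- as.numeric(instance)
  n_sets <- bitwShiftL(1L, N)
  nb <- nrow(problem$background)
  v <- numeric(n_sets)
  sizes <- integer(n_sets)
  # batch coalition evaluations in chunks to bound the stacked matrix
  chunk <- max(1L, floor(50000 / nb))
  s_all <- seq_len(n_sets) - 1L
  for (start in seq(1L, n_sets, by = chunk)) {
    ss <- s_all[start:min(n_sets, start + chunk - 1L)]
    big <- matrix(0, length(ss) * nb, N)
    colnames(big) <- problem$feature_names
    for (j in seq_along(ss)) {
      S <- which(bitwAnd(ss[j], bitwShiftL(1L, seq_len(N) - 1L)) != 0L)
      sizes[ss[j] + 1L] <- length(S)
      M <- problem$background
      if (length(S)) M[, S] <- matrix(instance[S], nb, length(S),
                                      byrow = TRUE)
      big[((j - 1L) * nb + 1L):(j * nb), ] <- M
    }
    pred <- problem$predict_fn(big)
    v[ss + 1L] <- colMeans(matrix(pred, nb, length(ss)))
  }
  lf <- lfactorial(0:N)
  wt <- exp(lf[0:(N - 1) + 1L] + lf[(N - 1):0 + 1L] - lf[N + 1L])
  phi <- numeric(N)
  for (i in seq_len(N)) {
    bit <- bitwShiftL(1L, i - 1L)
    without <- which(bitwAnd(seq_len(n_sets) - 1L, bit) == 0L)
    s_idx <- without
    phi[i] <- sum(wt[sizes[s_idx] + 1L] *
                  (v[s_idx + bit] - v[s_idx]))
  }
  names(phi) <- problem$feature_names
  structure(phi, base_value = problem$base_value,
            prediction = coalition_value(problem, instance, seq_len(N)))
}

#' Sampled Shapley values by permutation sampling
#'
#' Unbiased permutation-sampling estimator: for each sampled feature
#' ordering, the marginal contribution of each feature when added after
#' its predecessors is accumulated; per-feature Monte-Carlo standard
#' errors are reported.
#'
#' @param problem A [shapley_problem()].
#' @param instance Numeric vector to explain.
#' @param n_permutations Number of sampled orderings (>= 1).
#' @param seed Integer seed (deterministic estimates under a fixed seed).
#' @return Named numeric vector of attributions; attributes `se`
#'   (standard errors), `base_value`, `prediction`.
#' @export
sampled_shapley <- function(problem, instance, n_permutations = 200,
                            seed = 1L) {
  stopifnot(inherits(problem, "shapley_problem"), n_permutations >= 1)
  N <- length(problem$feature_names)
  instance <- as.numeric(instance)
  B <- problem$background
  nb <- nrow(B)
  withr_seed(seed, {
    contrib <- matrix(0, n_permutations, N)
    for (r in seq_len(n_permutations)) {
      perm <- sample.int(N)
      # one batched prediction per permutation: stack the N progressively
      # pinned background copies
      M <- B
      big <- matrix(0, N * nb, N)
      colnames(big) <- problem$feature_names
      for (k in seq_len(N)) {
        M[, perm[k]] <- instance[perm[k]]
        big[((k - 1L) * nb + 1L):(k * nb), ] <- M
      }
      pred <- problem$predict_fn(big)
      v <- colMeans(matrix(pred, nb, N))
      contrib[r, perm] <- diff(c(problem$base_value, v))
    }
    phi <- colMeans(contrib)
    se <- apply(contrib, 2, stats::sd) / sqrt(n_permutations)
    names(phi) <- names(se) <- problem$feature_names
    structure(phi, se = se, base_value = problem$base_value,
              prediction = coalition_value(problem, instance, seq_len(N)))
  })
}

#' Explain a set of instances
#'
#' Convenience wrapper computing one attribution vector per row.
#'
#' @param problem A [shapley_problem()].
#' @param instances Matrix/data.frame of rows to explain.
#' @param n_permutations Permutations per instance ([sampled_shapley()]);
#'   `exact = TRUE` uses enumeration instead (<= 15 features).
#' @param exact Use [exact_shapley()].
#' @param seed Integer seed.
#' @return Object of class `shap_explanation`: list with `phi` (instances
#'   x features matrix), `values` (the instances), `base_value`,
#'   `predictions`.
#' @export
explain_instances <- function(problem, instances, n_permutations = 200,
                              exact = FALSE, seed = 1L) {
  X <- as.matrix(instances)
  phi <- matrix(0, nrow(X), ncol(X),
                dimnames = list(NULL, problem$feature_names))
  preds <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    e <- if (exact) exact_shapley(problem, X[i, ])
         else sampled_shapley(problem, X[i, ], n_permutations,
                              seed = seed + i)
    phi[i, ] <- as.numeric(e)
    preds[i] <- attr(e, "prediction")
  }
  structure(list(phi = phi, values = X, base_value = problem$base_value,
                 predictions = preds),
            class = "shap_explanation")
}

#' Rank features by mean absolute attribution
#'
#' Ranks features by the mean |phi| across explained samples (descending,
#' ties broken lexicographically by feature name) and reports a direction
#' statistic: the Pearson correlation between the feature's value and its
#' attribution across samples (positive = high values push the prediction
#' up, mirroring the red/blue reading of SHAP summary plots).
#'
#' @param explanation A [explain_instances()] result.
#' @param top_k Number of features to keep (default 20); when larger than
#'   the feature count, all are returned with a `truncated = FALSE` flag.
#' @return data.frame: `rank`, `feature`, `mean_abs_phi`, `direction`.
#' @export
rank_features <- function(explanation, top_k = 20) {
  stopifnot(inherits(explanation, "shap_explanation"))
  phi <- explanation$phi
  vals <- explanation$values
  mabs <- colMeans(abs(phi))
  direction <- vapply(seq_len(ncol(phi)), function(j) {
    if (stats::sd(vals[, j]) < 1e-12 || stats::sd(phi[, j]) < 1e-12) {
      return(NA_real_)
    }
    stats::cor(vals[, j], phi[, j])
  }, numeric(1))
  ord <- order(-mabs, colnames(phi))
  k <- min(top_k, ncol(phi))
  out <- data.frame(rank = seq_len(k),
                    feature = colnames(phi)[ord][seq_len(k)],
                    mean_abs_phi = mabs[ord][seq_len(k)],
                    direction = direction[ord][seq_len(k)],
                    row.names = NULL)
  attr(out, "truncated") <- top_k < ncol(phi)
  out
}
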