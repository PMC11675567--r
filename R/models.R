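# The four model families and the seeded random-search tuner. The
# environment ships no tree/NN package, so the CART regression tree (used
# by the bagged forest and the boosting machine) and the one-hidden-layer
# perceptron are implemented here; the linear family wraps glmnet.

model_families <- function() {
  c("linear_logistic", "random_forest", "gradient_boosting",
    "feedforward_nn")
}

#' Model specification for the random-search tuner
#'
#' Describes a model family, a hyperparameter search space (a named list
#' of sampler functions, one draw per configuration) and a search budget.
#' The default spaces follow common practice: elastic-net mixing/strength
#' for the linear model; tree count 100-1000, depth 2-8 for the forest;
#' learning rate 1e-3-1e-1 for boosting; 8-64 hidden units with L2 decay
#' for the network.
#'
#' @param family One of `model_families()`.
#' @param search_space Named list of zero-argument sampler functions;
#'   `NULL` for the family default.
#' @param search_budget Number of sampled configurations (>= 1).
#' @param seed Integer seed for the search.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(family = c("linear_logistic", "random_forest",
                                  "gradient_boosting", "feedforward_nn"),
                       search_space = NULL, search_budget = 30, seed = 1L) {
  family <- match.arg(family)
  stopifnot(search_budget >= 1)
  if (is.null(search_space)) search_space <- default_search_space(family)
  structure(list(family = family, search_space = search_space,
                 search_budget = as.integer(search_budget),
                 seed = as.integer(seed)),
            class = "model_spec")
}

default_search_space <- function(family) {
  switch(family,
    linear_logistic = list(
      alpha = function() stats::runif(1),
      lambda = function() 10^stats::runif(1, -3, 0)),
    random_forest = list(
      n_trees = function() sample(100:1000, 1),
      mtry_frac = function() stats::runif(1, 0.05, 0.5),
      max_depth = function() sample(2:8, 1),
      min_node = function() sample(1:5, 1)),
    gradient_boosting = list(
      n_trees = function() sample(100:500, 1),
      max_depth = function() sample(2:8, 1),
      learning_rate = function() 10^stats::runif(1, -3, -1)),
    feedforward_nn = list(
      hidden = function() sample(8:64, 1),
      decay = function() 10^stats::runif(1, -4, 0),
      maxit = function() 150L))
}

draw_config <- function(space) lapply(space, function(f) f())

balanced_weights <- function(y) {
  n <- length(y); n1 <- sum(y == 1); n0 <- n - n1
  ifelse(y == 1, n / (2 * n1), n / (2 * n0))
}

# ---- preprocessing (fit on training data only) -------------------------

preproc_fit <- function(X, standardize) {
  X <- as.matrix(X)
  med <- apply(X, 2, stats::median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  Xi <- impute_with(X, med)
  mu <- colMeans(Xi); sdv <- apply(Xi, 2, stats::sd)
  sdv[sdv < 1e-12 | !is.finite(sdv)] <- 1
  list(medians = med, mu = mu, sd = sdv, standardize = standardize)
}

impute_with <- function(X, med) {
  for (j in seq_len(ncol(X))) {
    bad <- !is.finite(X[, j])
    if (any(bad)) X[bad, j] <- med[j]
  }
  X
}

preproc_apply <- function(pp, X) {
  X <- impute_with(as.matrix(X), pp$medians)
  if (pp$standardize) X <- sweep(sweep(X, 2, pp$mu), 2, pp$sd, "/")
  X
}

# ---- CART regression tree (compiled; see src/tree.cpp) ----------------

fit_tree <- function(X, y, w, max_depth, min_node, mtry) {
  .fit_tree_cpp(X, as.numeric(y), as.numeric(w), as.integer(max_depth),
                as.integer(min_node), as.integer(mtry))
}

tree_node_of <- function(tree, X) .tree_leaf_cpp(tree, X)

tree_predict <- function(tree, X) .predict_tree_cpp(tree, X)

# ---- families ----------------------------------------------------------

fit_family <- function(family, X, y, hyper, seed) {
  w <- balanced_weights(y)
  withr_seed(seed, switch(family,
    linear_logistic = {
      fit <- glmnet::glmnet(X, y, family = "binomial", weights = w,
                            alpha = hyper$alpha, lambda = hyper$lambda)
      list(kind = "glmnet", fit = fit, lambda = hyper$lambda)
    },
    random_forest = {
      mtry <- max(1L, round(hyper$mtry_frac * ncol(X)))
      n <- nrow(X)
      trees <- lapply(seq_len(hyper$n_trees), function(b) {
        bag <- sample.int(n, n, replace = TRUE)
        fit_tree(X[bag, , drop = FALSE], y[bag], w[bag],
                 hyper$max_depth, hyper$min_node, mtry)
      })
      list(kind = "forest", trees = trees)
    },
    gradient_boosting = {
      p0 <- sum(w * y) / sum(w)
      f0 <- log(p0 / (1 - p0))
      F <- rep(f0, length(y))
      trees <- vector("list", hyper$n_trees)
      for (m in seq_len(hyper$n_trees)) {
        p <- 1 / (1 + exp(-F))
        r <- y - p
        tr <- fit_tree(X, r, w, hyper$max_depth, 5L, ncol(X))
        leaf <- tree_node_of(tr, X)
        for (l in unique(leaf)) {
          in_l <- leaf == l
          num <- sum(w[in_l] * r[in_l])
          den <- sum(w[in_l] * p[in_l] * (1 - p[in_l])) + 1e-9
          tr$value[l] <- num / den
        }
        step <- tr$value[leaf]
        F <- F + hyper$learning_rate * step
        trees[[m]] <- tr
      }
      list(kind = "gbm", f0 = f0, lr = hyper$learning_rate, trees = trees)
    },
    feedforward_nn = {
      fit <- fit_mlp(X, y, w, hidden = hyper$hidden, decay = hyper$decay,
                     maxit = hyper$maxit)
      list(kind = "mlp", fit = fit)
    }))
}

predict_family <- function(fit, X) {
  X <- as.matrix(X)
  switch(fit$kind,
    glmnet = as.numeric(stats::predict(fit$fit, X, s = fit$lambda,
                                       type = "response")),
    forest = {
      p <- rowMeans(vapply(fit$trees, function(tr) tree_predict(tr, X),
                           numeric(nrow(X))))
      pmin(1, pmax(0, p))
    },
    gbm = {
      F <- rep(fit$f0, nrow(X))
      for (tr in fit$trees) F <- F + fit$lr * tree_predict(tr, X)
      1 / (1 + exp(-F))
    },
    mlp = predict_mlp(fit$fit, X))
}

# One-hidden-layer perceptron, tanh hidden units, logistic output,
# weighted cross-entropy + L2 decay, trained with analytic-gradient BFGS.
fit_mlp <- function(X, y, w, hidden, decay, maxit = 150L) {
  p <- ncol(X); h <- hidden
  n_w1 <- (p + 1L) * h
  unpack <- function(theta) {
    W1 <- matrix(theta[seq_len(n_w1)], p + 1L, h)
    W2 <- theta[(n_w1 + 1L):(n_w1 + h + 1L)]
    list(W1 = W1, W2 = W2)
  }
  Xb <- cbind(1, X)
  wn <- w / sum(w)
  loss <- function(theta) {
    par <- unpack(theta)
    H <- tanh(Xb %*% par$W1)
    z <- cbind(1, H) %*% par$W2
    pr <- 1 / (1 + exp(-z))
    pr <- pmin(1 - 1e-12, pmax(1e-12, pr))
    -sum(wn * (y * log(pr) + (1 - y) * log(1 - pr))) +
      decay * sum(theta^2) / 2
  }
  grad <- function(theta) {
    par <- unpack(theta)
    A <- Xb %*% par$W1
    H <- tanh(A)
    Hb <- cbind(1, H)
    z <- Hb %*% par$W2
    pr <- 1 / (1 + exp(-z))
    d2 <- wn * (pr - y)                       # n x 1
    gW2 <- crossprod(Hb, d2)
    dH <- (d2 %*% t(par$W2[-1])) * (1 - H^2)  # n x h
    gW1 <- crossprod(Xb, dH)
    c(as.numeric(gW1), as.numeric(gW2)) + decay * theta
  }
  theta0 <- stats::rnorm(n_w1 + h + 1L, 0, 1 / sqrt(p + 1))
  opt <- stats::optim(theta0, loss, grad, method = "BFGS",
                      control = list(maxit = maxit))
  c(unpack(opt$par), list(convergence = opt$convergence))
}

predict_mlp <- function(fit, X) {
  H <- tanh(cbind(1, X) %*% fit$W1)
  as.numeric(1 / (1 + exp(-(cbind(1, H) %*% fit$W2))))
}

# ---- tuner -------------------------------------------------------------

#' Tune hyperparameters by seeded random search and fit the final model
#'
#' Samples `search_budget` configurations from the spec's search space,
#' scores each by mean 5-fold (stratified) cross-validated PR-AUC on the
#' training set -- median imputation and (for the linear and network
#' families) z-scoring are fit inside each fold on the fold-train only --
#' and refits the best configuration on the full training set.
#'
#' @param X Training feature matrix or data.frame (numeric columns).
#' @param y 0/1 labels.
#' @param spec A [model_spec()].
#' @param config A [split_config()] (supplies `n_folds` and the fold
#'   seed).
#' @return Object of class `voicecog_model`: `family`, `hyper`,
#'   `cv_record` (data.frame of all configurations and mean CV PR-AUC),
#'   `best_cv_pr_auc`, fitted `preproc` and `fit`.
#' @export
tune_and_train <- function(X, y, spec, config = split_config()) {
  stopifnot(inherits(spec, "model_spec"))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.integer(y)
  standardize <- spec$family %in% c("linear_logistic", "feedforward_nn")
  folds <- stratified_folds(y, config$n_folds, config$seed)
  configs <- withr_seed(spec$seed, {
    lapply(seq_len(spec$search_budget), function(b) draw_config(spec$search_space))
  })
  cv_scores <- vapply(seq_along(configs), function(b) {
    hyper <- configs[[b]]
    fold_scores <- vapply(seq_len(config$n_folds), function(k) {
      tr <- folds != k; va <- !tr
      if (length(unique(y[va])) < 2L) return(NA_real_)
      pp <- preproc_fit(X[tr, , drop = FALSE], standardize)
      fit <- fit_family(spec$family, preproc_apply(pp, X[tr, , drop = FALSE]),
                        y[tr], hyper, seed = spec$seed + 1000L * b + k)
      sc <- predict_family(fit, preproc_apply(pp, X[va, , drop = FALSE]))
      pr_auc(sc, y[va])
    }, numeric(1))
    mean(fold_scores, na.rm = TRUE)
  }, numeric(1))
  if (all(!is.finite(cv_scores))) {
    stop("all configurations failed during cross-validation", call. = FALSE)
  }
  best <- which.max(cv_scores)
  pp <- preproc_fit(X, standardize)
  fit <- fit_family(spec$family, preproc_apply(pp, X), y, configs[[best]],
                    seed = spec$seed)
  cv_record <- data.frame(config = seq_along(configs),
                          mean_cv_pr_auc = cv_scores)
  structure(list(family = spec$family, hyper = configs[[best]],
                 cv_record = cv_record, best_cv_pr_auc = cv_scores[best],
                 preproc = pp, fit = fit,
                 feature_names = colnames(X)),
            class = "voicecog_model")
}

#' Predict positive-class probabilities
#'
#' @param object A [tune_and_train()] model.
#' @param newdata Feature matrix or data.frame with the training columns.
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
predict.voicecog_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(X))) {
    X <- X[, object$feature_names, drop = FALSE]
  }
  storage.mode(X) <- "double"
  predict_family(object$fit, preproc_apply(object$preproc, X))
}

#' Evaluate a fitted model on a held-out test set
#'
#' @param model A [tune_and_train()] model.
#' @param X_test,y_test Held-out features and 0/1 labels (both classes
#'   present).
#' @param counts Optional [task_counts()] for the baseline; defaults to
#'   the test-set counts.
#' @return An `eval_report` (see [evaluate_scores()]).
#' @export
evaluate_model <- function(model, X_test, y_test, counts = NULL) {
  evaluate_scores(predict(model, X_test), as.integer(y_test), counts)
}
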