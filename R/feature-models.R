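#' @name feature_models
#' @title Feature-based classifiers: linear SVM, RBF kSVM, random forest
#'
#' @description
#' The linear and RBF SVMs are tuned by an inner 10-fold cross-validated
#' grid search over dimensionality-reduction method, retained dimensions,
#' penalty C and (RBF only) kernel width gamma; the random forest uses a
#' fixed configuration (100 trees, minimum 2 samples to split, minimum 1
#' per leaf, no depth cap, Gini impurity) with no search. Max
#' normalization and reduction are re-fitted inside every inner fold, so
#' no tuner ever observes test rows.
NULL

#' Enumerate the SVM hyper-parameter grid
#'
#' Full Cartesian product of reduction method {pca, kbest}, retained
#' dimensions {60, 120, 210, 390, 570}, penalty C {1, 10, 100, 1000} and,
#' for the RBF kernel, gamma {0.1, 0.01, 0.001}: 120 configurations for
#' the RBF kernel, 40 for the linear kernel.
#'
#' @param kernel `"linear"` or `"rbf"`.
#' @param reductions,ks,Cs,gammas Optional restricted grids.
#' @return Data frame of configurations.
#' @export
enumerate_grid <- function(kernel = c("rbf", "linear"),
                           reductions = c("pca", "kbest"),
                           ks = c(60, 120, 210, 390, 570),
                           Cs = c(1, 10, 100, 1000),
                           gammas = c(0.1, 0.01, 0.001)) {
  kernel <- match.arg(kernel)
  if (kernel == "rbf")
    g <- expand.grid(reduction = reductions, k = ks, C = Cs, gamma = gammas,
                     stringsAsFactors = FALSE)
  else
    g <- expand.grid(reduction = reductions, k = ks, C = Cs,
                     stringsAsFactors = FALSE)
  g$kernel <- kernel
  g
}

# fit transforms + svm on (x, y) with one grid row; returns a closure-free
# model bundle usable on aligned raw feature matrices
fit_svm_config <- function(x, y, cfg) {
  mn <- fit_max_norm(x)
  xt <- apply_max_norm(x, mn)
  red <- fit_reduce(xt, y, method = cfg$reduction, k = min(cfg$k, ncol(xt)))
  xr <- apply_reduce(xt, red)
  fit <- e1071::svm(
    xr, as.factor(y),
    kernel = if (cfg$kernel == "rbf") "radial" else "linear",
    cost = cfg$C,
    gamma = if (cfg$kernel == "rbf") cfg$gamma else 1 / ncol(xr),
    scale = FALSE
  )
  list(type = "svm", config = cfg, max_norm = mn, reducer = red, fit = fit)
}

predict_model <- function(model, x) {
  if (model$type == "rf") {
    as.character(predict(model$fit, x))
  } else {
    xr <- apply_reduce(apply_max_norm(x, model$max_norm), model$reducer)
    as.character(predict(model$fit, xr))
  }
}

# deterministic stratified fold assignment
make_folds <- function(y, n_folds, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (lev in unique(y)) {
    idx <- sample(which(y == lev))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Tune (inner 10-fold CV grid search) and train a classifier
#'
#' For `"svm"`/`"ksvm"`: every grid configuration is scored by inner
#' 10-fold cross-validation on the training partition (max normalization
#' and reduction re-fitted inside each inner fold); the highest mean inner
#' accuracy wins, ties broken by smaller k, then smaller C, then larger
#' gamma; the final model is refitted on the full training partition with
#' the winning configuration. For `"rf"`: the fixed configuration, no
#' search.
#'
#' @param x Training feature matrix (rows = recordings).
#' @param y Training labels (two classes).
#' @param method `"svm"`, `"ksvm"` or `"rf"`.
#' @param seed Seed for fold assignment / forest growth.
#' @param grid Optional restricted grid (data frame from
#'   [enumerate_grid()]); defaults to the full grid for the method.
#' @param inner_folds Inner CV folds (default 10).
#' @return Fitted model bundle with `$config` and, for SVMs,
#'   `$score_table` (per-config mean inner accuracies).
#' @export
tune_and_train <- function(x, y, method = c("ksvm", "svm", "rf"),
                           seed = 1, grid = NULL, inner_folds = 10) {
  method <- match.arg(method)
  y <- as.character(y)
  if (length(unique(y)) < 2)
    stop("training labels contain a single class", call. = FALSE)

  if (method == "rf") {
    set.seed(seed)
    fit <- randomForest::randomForest(
      x, as.factor(y), ntree = 100, nodesize = 1, replace = TRUE)
    return(list(type = "rf", config = list(n_trees = 100, min_split = 2,
                                           min_leaf = 1, max_depth = NULL,
                                           criterion = "gini"),
                fit = fit))
  }

  kernel <- if (method == "ksvm") "rbf" else "linear"
  grid <- grid %||% enumerate_grid(kernel)
  if (nrow(grid) > 1) {
    fold <- make_folds(y, inner_folds, mix_seed(seed, 11))
    scores <- vapply(seq_len(nrow(grid)), function(ci) {
      cfg <- grid[ci, ]
      acc <- vapply(seq_len(inner_folds), function(f) {
        tr <- fold != f; te <- fold == f
        if (!any(te) || length(unique(y[tr])) < 2) return(NA_real_)
        m <- fit_svm_config(x[tr, , drop = FALSE], y[tr], cfg)
        mean(predict_model(m, x[te, , drop = FALSE]) == y[te])
      }, 0.0)
      mean(acc, na.rm = TRUE)
    }, 0.0)
    # ties: smaller k, then smaller C, then larger gamma
    ord <- order(-scores, grid$k, grid$C,
                 if (kernel == "rbf") -grid$gamma else grid$C)
    best <- grid[ord[1], ]
    score_table <- cbind(grid, inner_cv_accuracy = scores)
  } else {
    best <- grid[1, ]
    score_table <- cbind(grid, inner_cv_accuracy = NA_real_)
  }
  model <- fit_svm_config(x, y, best)
  model$score_table <- score_table
  model$inner_cv_accuracy <- if (nrow(grid) > 1) max(scores) else NA_real_
  model
}

#' Test-set accuracy of a fitted model
#'
#' @param model A [tune_and_train()] result.
#' @param x Test feature matrix (aligned columns, untouched during fit).
#' @param y True test labels.
#' @return Fraction of correct predictions in [0, 1].
#' @export
predict_accuracy <- function(model, x, y) {
  if (nrow(as.matrix(x)) == 0) stop("empty test set", call. = FALSE)
  mean(predict_model(model, as.matrix(x)) == as.character(y))
}
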