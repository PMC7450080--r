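#' @name feature_transforms
#' @title Train-set-fitted scaling and dimensionality reduction
#'
#' @description
#' Max normalization (subtract the training mean, divide by the training
#' maximum of the raw values, per feature) and two reductions fitted on the
#' training partition only: PCA and K-best (largest one-way ANOVA F between
#' classes). Fit functions never receive test rows; the fitted parameters
#' are applied identically to train and test.
NULL

#' Fit max-normalization parameters on a training matrix
#'
#' @param train Numeric matrix (rows = training recordings, named columns).
#' @return List with `mu` (column means), `M` (column maxima of the raw
#'   values), `feature_names`; class `max_norm_params`.
#' @export
fit_max_norm <- function(train) {
  train <- as.matrix(train)
  if (nrow(train) < 1) stop("empty training matrix", call. = FALSE)
  structure(
    list(mu = colMeans(train), M = apply(train, 2, max),
         feature_names = colnames(train)),
    class = "max_norm_params"
  )
}

#' Apply max normalization
#'
#' `t(x) = (x - mu) / M` per column, with the guard `M = 0 -> 0`. The same
#' parameters must be used for the training and the test partition.
#'
#' @param x Matrix with the same named columns as the fit.
#' @param params A [fit_max_norm()] result.
#' @return Transformed matrix.
#' @export
apply_max_norm <- function(x, params) {
  x <- as.matrix(x)
  if (!is.null(params$feature_names) && !is.null(colnames(x)) &&
      !identical(colnames(x), params$feature_names))
    stop("feature names do not match the fitted parameters", call. = FALSE)
  M <- params$M
  out <- sweep(x, 2, params$mu)
  out <- sweep(out, 2, ifelse(M == 0, 1, M), "/")
  out[, M == 0] <- 0
  out
}

#' Fit a dimensionality reduction on the (transformed) training matrix
#'
#' `method = "pca"`: the top-k variance-ordered principal components of the
#' training rows (centered on training means, no re-standardization).
#' `method = "kbest"`: the k features with the largest one-way ANOVA F
#' statistic between the two classes.
#'
#' @param train Numeric matrix (max-normalized training rows).
#' @param labels Class labels (required for `"kbest"`; two classes).
#' @param method `"pca"` or `"kbest"`.
#' @param k Number of output dimensions, `k <= ncol(train)`.
#' @return A `reducer` object for [apply_reduce()].
#' @export
fit_reduce <- function(train, labels = NULL, method = c("pca", "kbest"), k) {
  method <- match.arg(method)
  train <- as.matrix(train)
  if (k > ncol(train)) stop("k exceeds the feature count", call. = FALSE)
  if (method == "pca") {
    pc <- prcomp(train, center = TRUE, scale. = FALSE, rank. = k)
    red <- list(method = "pca", k = k, center = pc$center,
                rotation = pc$rotation,
                explained_var = pc$sdev[seq_len(k)]^2)
  } else {
    if (is.null(labels) || length(unique(labels)) != 2)
      stop("kbest needs two-class labels", call. = FALSE)
    f <- anova_f_scores(train, labels)
    keep <- order(f, decreasing = TRUE)[seq_len(k)]
    keep <- sort(keep)                     # stable column order
    red <- list(method = "kbest", k = k, keep = keep, scores = f)
  }
  structure(red, class = "reducer")
}

#' One-way ANOVA F score per feature
#'
#' Between-class over within-class mean squares, column-wise; 0 for
#' zero-variance columns.
#'
#' @param x Numeric matrix.
#' @param labels Class labels.
#' @return Numeric vector of F statistics, one per column.
#' @export
anova_f_scores <- function(x, labels) {
  labels <- as.factor(labels)
  n <- nrow(x); g <- nlevels(labels)
  gm <- colMeans(x)
  ssb <- 0; ssw <- 0
  for (lev in levels(labels)) {
    rows <- labels == lev
    m <- colMeans(x[rows, , drop = FALSE])
    ssb <- ssb + sum(rows) * (m - gm)^2
    ssw <- ssw + colSums(sweep(x[rows, , drop = FALSE], 2, m)^2)
  }
  f <- (ssb / (g - 1)) / (ssw / (n - g))
  f[!is.finite(f)] <- 0
  f
}

#' Apply a fitted reducer to an aligned matrix
#'
#' @param x Matrix with the same columns the reducer was fitted on.
#' @param reducer A [fit_reduce()] result.
#' @return Reduced matrix (`k` columns).
#' @export
apply_reduce <- function(x, reducer) {
  x <- as.matrix(x)
  if (reducer$method == "pca")
    sweep(x, 2, reducer$center) %*% reducer$rotation
  else
    x[, reducer$keep, drop = FALSE]
}
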