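#' @name evaluation_significance
#' @title Balanced tasks, the ten-split protocol and the random-label null
#'
#' @description
#' A classification task compares two medication classes within one
#' pathology stratum on class-balanced recordings. The protocol draws ten
#' independent seeded random 90/10 train/test splits, fits all transforms
#' and tuning on the training partition only, and records the ten test
#' accuracies. The random-label null repeats the identical protocol with
#' training labels shuffled within each split (test labels untouched).
#' Significance of the correct-vs-null accuracy vectors is assessed with
#' an in-package Kruskal-Wallis statistic (chi-square approximation, tie
#' correction), with significance tiers `*` at P < .01 and `**` at
#' P < .001.
NULL

#' Balance a two-class task by down-sampling the majority class
#'
#' Within the task's stratum, the majority class is down-sampled uniformly
#' at random (seeded, without replacement) to the minority count; the
#' output holds `2 * min(n_a, n_b)` recordings.
#'
#' @param labels_table Data frame with `recording_id`, `medication_class`,
#'   `eeg_status` (from [label_cohort()]), or any table with those columns.
#' @param class_a,class_b The two medication classes.
#' @param stratum `"normal"` or `"abnormal"` (or `NULL` to ignore the
#'   stratum).
#' @param seed Seed for the down-sampling draw.
#' @return The balanced subset of `labels_table` (rows of both classes).
#' @export
balance_classes <- function(labels_table, class_a, class_b,
                            stratum = NULL, seed = 1) {
  stopifnot(class_a != class_b)
  tab <- labels_table
  if (!is.null(stratum)) tab <- tab[tab$eeg_status == stratum, , drop = FALSE]
  a <- tab[tab$medication_class == class_a, , drop = FALSE]
  b <- tab[tab$medication_class == class_b, , drop = FALSE]
  if (nrow(a) == 0) stop("no recordings for class ", class_a, call. = FALSE)
  if (nrow(b) == 0) stop("no recordings for class ", class_b, call. = FALSE)
  m <- min(nrow(a), nrow(b))
  set.seed(mix_seed(seed, 101))
  if (nrow(a) > m) a <- a[sample(nrow(a), m), , drop = FALSE]
  if (nrow(b) > m) b <- b[sample(nrow(b), m), , drop = FALSE]
  out <- rbind(a, b)
  rownames(out) <- NULL
  out
}

#' Ten stratified random 90/10 train/test partitions
#'
#' Each repetition is an independent seeded random partition with test
#' size `floor(test_frac * n_total)`, allocated as evenly as possible
#' across the two classes (any odd remainder goes to the first class);
#' train and test are disjoint and exhaustive.
#'
#' @param labels Class label per recording (length `n_total`).
#' @param n_reps Number of repetitions (10).
#' @param test_frac Test fraction (0.1).
#' @param seed Master seed; repetition r uses a seed derived from
#'   `(seed, r)`.
#' @return List of `n_reps` lists with integer `train` and `test` indices.
#' @export
repeated_splits <- function(labels, n_reps = 10, test_frac = 0.1, seed = 1) {
  labels <- as.character(labels)
  n <- length(labels)
  if (n < 20) stop("need at least 20 recordings", call. = FALSE)
  n_test <- floor(test_frac * n)
  if (n_test < 1) stop("test set would be empty", call. = FALSE)
  classes <- sort(unique(labels))
  # even allocation of the test quota across classes
  quota <- rep(n_test %/% length(classes), length(classes))
  extra <- n_test - sum(quota)
  if (extra > 0) quota[seq_len(extra)] <- quota[seq_len(extra)] + 1
  lapply(seq_len(n_reps), function(r) {
    set.seed(mix_seed(seed, 1000 + r))
    test <- unlist(lapply(seq_along(classes), function(ci) {
      idx <- which(labels == classes[ci])
      sample(idx, min(quota[ci], length(idx)))
    }))
    test <- sort(test)
    list(train = setdiff(seq_len(n), test), test = test)
  })
}

#' Run the ten-split protocol for one classifier
#'
#' For each split: transforms and tuning are fitted on the training
#' partition only, then the fitted model is scored on the held-out test
#' partition. Feature-based methods (`"svm"`, `"ksvm"`, `"rf"`) consume a
#' feature matrix; network methods (`"lnn"`, `"scnn"`, `"dcnn"`,
#' `"eegnet"`) consume segments.
#'
#' @param x Feature matrix (rows = recordings) for feature methods, or a
#'   list of segments for network methods.
#' @param labels Class label per recording.
#' @param method One of the seven classifiers.
#' @param seed Master seed (drives splits, tuning folds, model fits).
#' @param n_reps Number of splits (10).
#' @param grid Restricted SVM grid (see [tune_and_train()]).
#' @param shuffle_train_labels If `TRUE`, training labels are shuffled
#'   (seeded per split) before fitting: the random-label null. Test labels
#'   are never touched.
#' @param network_config [train_two_run()] config for network methods.
#' @param network_opts Architecture overrides for network methods.
#' @return A `cv_result`: `accuracies` (length `n_reps`), `configs`,
#'   `n_total`, `n_test`, `method`.
#' @export
run_protocol <- function(x, labels, method = c("ksvm", "svm", "rf", "lnn",
                                               "scnn", "dcnn", "eegnet"),
                         seed = 1, n_reps = 10, grid = NULL,
                         shuffle_train_labels = FALSE,
                         network_config = list(), network_opts = list()) {
  method <- match.arg(method)
  labels <- as.character(labels)
  splits <- repeated_splits(labels, n_reps = n_reps, seed = seed)
  is_net <- method %in% c("lnn", "scnn", "dcnn", "eegnet")
  accs <- numeric(n_reps)
  configs <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    tr <- splits[[r]]$train; te <- splits[[r]]$test
    y_tr <- labels[tr]
    if (shuffle_train_labels) {
      set.seed(mix_seed(seed, 5000 + r))
      y_tr <- sample(y_tr)
    }
    if (is_net) {
      seg_tr <- x[tr]; seg_te <- x[te]
      dims <- dim(if (is.matrix(seg_tr[[1]])) seg_tr[[1]] else
        seg_tr[[1]]$data)
      net <- build_network(method, input_shape = dims,
                           seed = mix_seed(seed, 100 + r),
                           opts = network_opts)
      cfg <- modifyList(list(seed = mix_seed(seed, 200 + r)),
                        network_config)
      trained <- train_two_run(net, seg_tr, y_tr, cfg)
      accs[r] <- network_predict_accuracy(trained, seg_te, labels[te])
      configs[[r]] <- list(arch = method, best_epoch = trained$best_epoch)
    } else {
      model <- tune_and_train(x[tr, , drop = FALSE], y_tr, method,
                              seed = mix_seed(seed, 300 + r), grid = grid)
      accs[r] <- predict_accuracy(model, x[te, , drop = FALSE], labels[te])
      configs[[r]] <- model$config
    }
  }
  structure(
    list(accuracies = accs, configs = configs,
         n_total = length(labels), n_test = length(splits[[1]]$test),
         method = method, random_labels = shuffle_train_labels),
    class = "cv_result"
  )
}

#' Random-label null protocol
#'
#' Identical to [run_protocol()] except that training labels are shuffled
#' (seeded) within each split before any fitting; test labels remain true.
#'
#' @inheritParams run_protocol
#' @return A `cv_result`.
#' @export
random_label_null <- function(x, labels, method = "ksvm", seed = 1,
                              n_reps = 10, grid = NULL,
                              network_config = list(),
                              network_opts = list()) {
  run_protocol(x, labels, method, seed = seed, n_reps = n_reps, grid = grid,
               shuffle_train_labels = TRUE,
               network_config = network_config, network_opts = network_opts)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result %s%s: n_total %d, n_test %d, accuracy %.3f +/- %.3f>\n",
              x$method, if (isTRUE(x$random_labels)) " (random labels)" else "",
              x$n_total, x$n_test, mean(x$accuracies), sd(x$accuracies)))
  invisible(x)
}

#' Kruskal-Wallis test for two accuracy vectors
#'
#' In-package implementation: joint mid-rank ranking,
#' `H = 12 / (N (N + 1)) * sum(R_i^2 / n_i) - 3 (N + 1)` divided by the
#' tie-correction factor `1 - sum(t^3 - t) / (N^3 - N)`, with the P-value
#' from the chi-square distribution with 1 degree of freedom (two groups).
#' All values identical across both groups gives H = 0, p = 1.
#'
#' @param a,b Non-empty numeric vectors (e.g. two accuracy vectors).
#' @return A `significance_result`: `H`, `p`, `tier` (`"ns"`, `"*"` for
#'   p < .01, `"**"` for p < .001).
#' @export
kruskal_wallis <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  x <- c(a, b)
  g <- rep(1:2, c(length(a), length(b)))
  N <- length(x)
  if (length(unique(x)) == 1) {
    return(structure(list(H = 0, p = 1, tier = "ns"),
                     class = "significance_result"))
  }
  r <- rank(x)                               # mid-ranks for ties
  R1 <- sum(r[g == 1]); R2 <- sum(r[g == 2])
  H <- 12 / (N * (N + 1)) *
    (R1^2 / length(a) + R2^2 / length(b)) - 3 * (N + 1)
  ties <- table(x)
  tie_corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (tie_corr > 0) H <- H / tie_corr
  p <- pchisq(H, df = 1, lower.tail = FALSE)
  structure(list(H = H, p = p, tier = significance_tier(p)),
            class = "significance_result")
}

significance_tier <- function(p) {
  if (p < 0.001) "**" else if (p < 0.01) "*" else "ns"
}

#' @export
print.significance_result <- function(x, ...) {
  cat(sprintf("<kruskal-wallis H = %.4f, p = %.4g [%s]>\n", x$H, x$p, x$tier))
  invisible(x)
}

#' Significance of correct-label vs. random-label results
#'
#' Applies [kruskal_wallis()] to the two ten-accuracy vectors and assigns
#' the significance tier. Non-significant results mean the labels were
#' non-informative for the classifier.
#'
#' @param correct `cv_result` from [run_protocol()].
#' @param null `cv_result` from [random_label_null()].
#' @return A `significance_result` with added `mean_accuracy`,
#'   `null_mean_accuracy`.
#' @export
significance_report <- function(correct, null) {
  res <- kruskal_wallis(correct$accuracies, null$accuracies)
  res$mean_accuracy <- mean(correct$accuracies)
  res$null_mean_accuracy <- mean(null$accuracies)
  res
}

#' Pairwise Kruskal-Wallis comparisons of accuracy vectors
#'
#' Utility mirroring cross-task / cross-method contrasts: every pair of
#' the supplied `cv_result`s (or bare numeric vectors) is tested.
#'
#' @param results Named list of `cv_result`s or numeric vectors.
#' @return Data frame: `a`, `b`, `H`, `p`, `tier`.
#' @export
compare_cv_results <- function(results) {
  nms <- names(results) %||% as.character(seq_along(results))
  vecs <- lapply(results, function(r)
    if (inherits(r, "cv_result")) r$accuracies else r)
  pairs <- utils::combn(seq_along(vecs), 2)
  do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    kw <- kruskal_wallis(vecs[[i1]], vecs[[i2]])
    data.frame(a = nms[i1], b = nms[i2], H = kw$H, p = kw$p,
               tier = kw$tier, stringsAsFactors = FALSE)
  }))
}
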