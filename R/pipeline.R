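#' @name pipeline
#' @title End-to-end conveniences
#'
#' @description
#' Helpers chaining the pipeline stages: streaming feature extraction for
#' synthetic cohorts (one recording in memory at a time), cohort loading
#' from an EDF directory, and a one-call task evaluation (balance, ten
#' splits, random-label null, significance).
NULL

#' Generate a cohort and compute its feature matrix, streaming
#'
#' Equivalent to `feature_matrix(preprocess_cohort(generate_cohort(spec)))`
#' but holds only one recording in memory at a time, which matters at
#' cohort scale. Recordings rejected by preprocessing are dropped (with
#' their reasons attached).
#'
#' @param spec A [cohort_spec()].
#' @return List with `x` (features), `labels`, `ids`, and attribute
#'   `"omitted"`.
#' @export
cohort_feature_matrix <- function(spec) {
  n_feat <- length(qeeg_feature_names())
  rows <- list(); labels <- character(0); ids <- character(0)
  omitted <- character(0)
  for (cl in spec$classes) {
    for (sid in seq_len(spec$n_per_class)) {
      rec <- generate_recording(spec, cl, sid)
      seg <- preprocess_recording(rec)
      if (is_omitted(seg)) {
        omitted[rec$id] <- seg$reason
        next
      }
      rows[[length(rows) + 1]] <- feature_vector(seg)
      labels <- c(labels, cl)
      ids <- c(ids, rec$id)
    }
  }
  x <- do.call(rbind, rows)
  rownames(x) <- ids
  out <- list(x = x, labels = labels, ids = ids)
  attr(out, "omitted") <- omitted
  out
}

#' Load a cohort written by [generate_cohort()] from disk
#'
#' Reads every `<id>.edf` with its `<id>.txt` sidecar report.
#'
#' @param dir Directory with EDF + report pairs.
#' @return List of entries `list(recording, report, id)`.
#' @export
read_cohort <- function(dir) {
  edfs <- sort(list.files(dir, pattern = "\\.edf$", full.names = TRUE))
  lapply(edfs, function(path) {
    id <- sub("\\.edf$", "", basename(path))
    txt <- file.path(dir, paste0(id, ".txt"))
    list(recording = read_edf(path),
         report = if (file.exists(txt))
           paste(readLines(txt), collapse = "\n") else NULL,
         id = id)
  })
}

#' Evaluate one balanced classification task end to end
#'
#' Balances the two classes, runs the ten-split protocol with correct and
#' with shuffled training labels, and reports the Kruskal-Wallis
#' significance of the contrast.
#'
#' @param x Feature matrix (feature methods) or segment list (network
#'   methods), rows/entries aligned with `labels`.
#' @param labels Medication class per recording.
#' @param class_a,class_b The two classes to contrast.
#' @param method One of the seven classifiers.
#' @param seed Master seed.
#' @param ... Passed to [run_protocol()] (e.g. `grid`).
#' @return List with `correct`, `null` (`cv_result`s) and `significance`.
#' @export
evaluate_task <- function(x, labels, class_a, class_b, method = "ksvm",
                          seed = 1, ...) {
  labels <- as.character(labels)
  keep <- labels %in% c(class_a, class_b)
  labels <- labels[keep]
  x <- if (is.matrix(x)) x[keep, , drop = FALSE] else x[keep]
  counts <- table(labels)
  m <- min(counts)
  sel <- unlist(lapply(names(counts), function(cl) {
    idx <- which(labels == cl)
    if (length(idx) > m) { set.seed(mix_seed(seed, 77)); sample(idx, m) }
    else idx
  }))
  sel <- sort(sel)
  labels <- labels[sel]
  x <- if (is.matrix(x)) x[sel, , drop = FALSE] else x[sel]
  correct <- run_protocol(x, labels, method, seed = seed, ...)
  null <- random_label_null(x, labels, method, seed = mix_seed(seed, 13), ...)
  list(correct = correct, null = null,
       significance = significance_report(correct, null))
}
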