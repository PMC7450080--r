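#' @name qeeg_features
#' @title The 570-dimensional qEEG feature battery
#'
#' @description
#' Thirty features per channel, 19 channels, 570 in total. Per channel:
#' six absolute and six relative band powers (delta, theta, alpha, mu,
#' beta, gamma), entropy of the periodogram and of the normalized
#' periodogram, and sixteen time-domain descriptors (signal entropy,
#' mean-thresholded Lempel-Ziv complexity, curve length, energy, non-linear
#' (Teager) energy, sixth power, min, max, median, variance, standard
#' deviation, skew, kurtosis, integral, Hjorth mobility and complexity).
#' All entropies use the natural logarithm; variance-type moments use the
#' n denominator; kurtosis is non-excess. The classical battery also lists
#' a "sum" feature; at fixed sampling rate it is an exact scalar multiple
#' of the integral, so the default registry drops it to reach 30 per
#' channel (re-enable via `qeeg_feature_names(include_sum = TRUE)`).
NULL

#' One-sided periodogram
#'
#' Non-averaged, rectangular-window PSD estimate on the full segment. The
#' scaling is such that the integrated (summed) power equals the signal's
#' mean square: for a zero-mean signal, total power recovers the variance
#' (Parseval).
#'
#' @param x Finite numeric signal, length >= 2.
#' @param fs Sampling rate in Hz.
#' @return List with `freqs` (Hz, 0..fs/2), `power` (>= 0), `fs`,
#'   `n_samples`; class `periodogram`.
#' @export
periodogram <- function(x, fs) {
  if (!all(is.finite(x))) stop("non-finite input", call. = FALSE)
  n <- length(x)
  stopifnot(n >= 2)
  X <- fft(x)
  nh <- n %/% 2 + 1
  p <- (Mod(X[seq_len(nh)])^2) / n^2
  # fold the negative-frequency half in (all bins except DC and, for even
  # n, Nyquist appear twice in the full spectrum)
  dbl <- 2:(nh - if (n %% 2 == 0) 1 else 0)
  p[dbl] <- 2 * p[dbl]
  structure(list(freqs = (seq_len(nh) - 1) * fs / n, power = p,
                 fs = fs, n_samples = n),
            class = "periodogram")
}

#' Absolute and relative band powers
#'
#' Absolute power: sum of the PSD over bins with `lo <= f < hi`. Relative
#' power: absolute divided by the total power over all bins (0 when total
#' power is 0).
#'
#' @param psd A [periodogram()].
#' @param bands Band table (default [EEG_BANDS]).
#' @return Named numeric vector of 12 values: `abs_<band>` then
#'   `rel_<band>`.
#' @export
band_powers <- function(psd, bands = EEG_BANDS) {
  total <- sum(psd$power)
  absb <- vapply(seq_len(nrow(bands)), function(i) {
    sel <- psd$freqs >= bands$lo[i] & psd$freqs < bands$hi[i]
    sum(psd$power[sel])
  }, 0.0)
  relb <- if (total > 0) absb / total else rep(0, length(absb))
  stats::setNames(c(absb, relb),
                  c(paste0("abs_", bands$name), paste0("rel_", bands$name)))
}

#' Entropy of the periodogram and of the normalized periodogram
#'
#' Shannon entropy (natural log, `0 * log 0 := 0`): `H_norm` on the PSD
#' normalized to a probability distribution; `H_raw` on the raw PSD values
#' themselves. Both 0 for an all-zero PSD.
#'
#' @param psd A [periodogram()].
#' @return Named vector `c(spec_entropy_raw, spec_entropy_norm)`.
#' @export
spectral_entropies <- function(psd) {
  p <- psd$power
  xlogx <- function(v) { out <- v * log(v); out[v == 0] <- 0; out }
  if (sum(p) == 0)
    return(c(spec_entropy_raw = 0, spec_entropy_norm = 0))
  q <- p / sum(p)
  c(spec_entropy_raw = -sum(xlogx(p)),
    spec_entropy_norm = -sum(xlogx(q)))
}

#' Mean-thresholded Lempel-Ziv complexity
#'
#' Binarizes the signal at its arithmetic mean (`x >= mean -> 1`) and
#' counts LZ76 exhaustive-history phrases. Reported as the raw phrase
#' count, invariant under any positive affine transform of the signal.
#'
#' @param x Numeric signal.
#' @return Integer phrase count.
#' @export
lempel_ziv_complexity <- function(x) {
  .lz76_count(as.integer(x >= mean(x)))
}

#' The sixteen time-domain features of one channel
#'
#' See the package-level description for definitions. Degenerate (constant)
#' signals return 0 for entropy, mobility, complexity, skew and kurtosis.
#'
#' @param x Finite numeric signal, length >= 3.
#' @param fs Sampling rate in Hz (used by the integral).
#' @return Named numeric vector of 16 values.
#' @export
time_features <- function(x, fs) {
  if (!all(is.finite(x))) stop("non-finite input", call. = FALSE)
  stopifnot(length(x) >= 3)
  .time_features_cpp(as.numeric(x), fs)
}

#' Ordered feature names of the default battery
#'
#' @param channels Channel names (default the canonical 19).
#' @param include_sum Re-enable the redundant `sum` feature (31/channel).
#' @return Character vector, channel-major (`"Fp1__abs_delta"`, ...).
#' @export
qeeg_feature_names <- function(channels = CANONICAL_CHANNELS,
                               include_sum = FALSE) {
  per_channel <- c(paste0("abs_", EEG_BANDS$name),
                   paste0("rel_", EEG_BANDS$name),
                   "spec_entropy_raw", "spec_entropy_norm",
                   "signal_entropy", "lzc", "curve_length", "energy",
                   "nonlinear_energy", "sixth_power", "min", "max",
                   "median", "variance", "std", "skew", "kurtosis",
                   "integral", if (include_sum) "sum", "mobility",
                   "complexity")
  as.vector(t(outer(channels, per_channel, paste, sep = "__")))
}

#' Compute the feature vector of one canonical segment
#'
#' 30 features per channel (12 band powers, 2 spectral entropies, 16
#' time-domain descriptors), concatenated channel-major: 570 named finite
#' values.
#'
#' @param seg A `canonical_segment` (or any channels x samples matrix with
#'   a `fs` attribute structure; lists with `$data` and `$fs` accepted).
#' @param include_sum Include the redundant `sum` feature (31/channel).
#' @return Named numeric vector, length 570 (or 589 with `sum`).
#' @export
feature_vector <- function(seg, include_sum = FALSE) {
  data <- seg$data; fs <- seg$fs
  n <- ncol(data)
  channels <- rownames(data) %||% paste0("ch", seq_len(nrow(data)))
  # all channel spectra in one batched FFT; arithmetic matches the
  # single-channel periodogram()/band_powers()/spectral_entropies() path
  X <- stats::mvfft(t(data))
  nh <- n %/% 2 + 1
  dbl <- 2:(nh - if (n %% 2 == 0) 1 else 0)
  freqs <- (seq_len(nh) - 1) * fs / n
  P <- Mod(X[seq_len(nh), , drop = FALSE])^2 / n^2
  P[dbl, ] <- 2 * P[dbl, ]
  band_mask <- t(vapply(seq_len(nrow(EEG_BANDS)), function(i)
    as.numeric(freqs >= EEG_BANDS$lo[i] & freqs < EEG_BANDS$hi[i]),
    numeric(nh)))
  total <- colSums(P)
  absB <- band_mask %*% P                      # 6 x channels
  relB <- sweep(absB, 2, ifelse(total > 0, total, 1), "/")
  relB[, total == 0] <- 0
  xlogx <- function(v) { out <- v * log(v); out[v == 0] <- 0; out }
  h_raw <- -colSums(xlogx(P))
  Q <- sweep(P, 2, ifelse(total > 0, total, 1), "/")
  h_norm <- -colSums(xlogx(Q))
  h_raw[total == 0] <- 0; h_norm[total == 0] <- 0
  out <- lapply(seq_len(nrow(data)), function(i) {
    tf <- time_features(data[i, ], fs)
    if (include_sum)
      tf <- append(tf, c(sum = sum(data[i, ])),
                   after = which(names(tf) == "integral"))
    c(absB[, i], relB[, i], h_raw[i], h_norm[i], tf)
  })
  v <- unlist(out)
  names(v) <- qeeg_feature_names(channels, include_sum)
  stopifnot(all(is.finite(v)))
  v
}

#' Feature matrix of a cohort of segments
#'
#' @param segments List of `canonical_segment`s (e.g. from
#'   [preprocess_cohort()]).
#' @return List with `x` (matrix, one row per recording, 570 named
#'   columns), `labels` (truth classes where available), `ids`.
#' @export
feature_matrix <- function(segments) {
  x <- t(vapply(segments, feature_vector,
                numeric(length(qeeg_feature_names()))))
  rownames(x) <- vapply(segments, function(s)
    as.character(s$id %||% ""), "")
  labels <- vapply(segments, function(s)
    s$truth$class %||% NA_character_, "")
  list(x = x, labels = labels, ids = rownames(x))
}

#' The feature registry
#'
#' Documents every formula choice of the battery, one row per per-channel
#' feature; serializable to JSON for provenance.
#'
#' @return Data frame with `feature` and `definition`.
#' @export
feature_registry <- function() {
  data.frame(
    feature = c(paste0("abs_", EEG_BANDS$name), paste0("rel_", EEG_BANDS$name),
                "spec_entropy_raw", "spec_entropy_norm", "signal_entropy",
                "lzc", "curve_length", "energy", "nonlinear_energy",
                "sixth_power", "min", "max", "median", "variance", "std",
                "skew", "kurtosis", "integral", "mobility", "complexity"),
    definition = c(
      sprintf("sum of one-sided periodogram over %g <= f < %g Hz",
              EEG_BANDS$lo, EEG_BANDS$hi),
      sprintf("absolute %s power / total power over all bins",
              EEG_BANDS$name),
      "-sum(S * ln S) over raw periodogram values (0 ln 0 := 0)",
      "-sum(p * ln p), p = S / sum(S)",
      "Shannon entropy of 100-bin histogram of z-scored signal on [-5, 5]",
      "LZ76 phrase count of binarized signal (x >= mean -> 1)",
      "sum |x[n] - x[n-1]|",
      "sum x^2",
      "sum (x[n]^2 - x[n-1] x[n+1]) (Teager)",
      "sum x^6",
      "min(x)", "max(x)", "median(x)",
      "mean squared deviation (n denominator)",
      "sqrt(variance)",
      "standardized third central moment",
      "standardized fourth central moment (non-excess)",
      "sum(x) / fs",
      "sqrt(var(diff x) / var x)",
      "mobility(diff x) / mobility(x)"
    ),
    stringsAsFactors = FALSE
  )
}
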