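#' Construct an EEG recording object
#'
#' Lightweight container for a labeled multichannel time series at any
#' pipeline stage: a channels x samples matrix in microvolts, channel names,
#' and a sampling rate.
#'
#' @param data Numeric matrix, channels x samples.
#' @param channels Character vector of channel names (length `nrow(data)`).
#' @param fs Sampling rate in Hz (> 0).
#' @param truth Optional list with ground-truth information (synthetic data).
#' @param id Optional recording identifier.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, channels, fs, truth = NULL, id = NULL) {
  if (!is.matrix(data)) data <- as.matrix(data)
  stopifnot(is.numeric(data), length(channels) == nrow(data), fs > 0)
  structure(
    list(data = data, channels = as.character(channels), fs = fs,
         truth = truth, id = id),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording%s: %d channels x %d samples @ %g Hz (%.1f s)>\n",
              if (!is.null(x$id)) paste0(" ", x$id) else "",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Specify a synthetic EEG cohort
#'
#' Defines the study conditions for a generated cohort: how many recordings
#' per medication class, which classes, the per-class multiplicative
#' band-power modifiers ("planted effects"), the sampling rate and duration,
#' and the pathology impression written into each report.
#'
#' Band factors multiply the *power* in the named band; a factor of 0.5 for
#' `alpha` halves that class's expected absolute alpha power, 1 leaves it at
#' the neutral 1/f-like profile.
#'
#' @param n_per_class Recordings per class (>= 1).
#' @param classes Subset of `c("dilantin", "keppra", "none")`.
#' @param effect Named list: per class, a named numeric vector of band-power
#'   factors (names among `EEG_BANDS$name`), all finite and >= 0. Classes not
#'   listed get all-1 factors.
#' @param sampling_rate Hz, one of the clinically common rates
#'   (100, 250, 256, 500 all exercised in tests); any value > 0 accepted.
#' @param duration Recording length in seconds (default 420 = 7 min;
#'   values below 360 s deliberately produce recordings the preprocessing
#'   stage must reject).
#' @param pathology `"normal"` or `"abnormal"`; written into report text.
#' @param seed Integer master seed; every recording is reproducible from
#'   `(seed, subject index)`.
#' @param distractors If `TRUE`, recordings also carry A1, A2 and EKG
#'   channels (to exercise channel selection).
#' @param drop_channel Optional canonical channel name to omit from every
#'   recording (to exercise the omission rule).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_class,
                        classes = c("dilantin", "keppra", "none"),
                        effect = list(),
                        sampling_rate = 100,
                        duration = 420,
                        pathology = "abnormal",
                        seed = 1,
                        distractors = FALSE,
                        drop_channel = NULL) {
  classes <- match.arg(classes, c("dilantin", "keppra", "none"),
                       several.ok = TRUE)
  stopifnot(n_per_class >= 1, duration >= 0, sampling_rate > 0)
  pathology <- match.arg(pathology, c("normal", "abnormal"))
  for (cl in names(effect)) {
    if (!cl %in% classes)
      stop("effect given for unknown class: ", cl)
    fac <- effect[[cl]]
    if (!all(is.finite(fac)) || any(fac < 0))
      stop("band factors must be finite and >= 0")
    if (!all(names(fac) %in% EEG_BANDS$name))
      stop("unknown band name in effect for class ", cl)
  }
  structure(
    list(n_per_class = as.integer(n_per_class), classes = classes,
         effect = effect, sampling_rate = sampling_rate,
         duration = duration, pathology = pathology,
         seed = as.integer(seed), distractors = isTRUE(distractors),
         drop_channel = drop_channel),
    class = "cohort_spec"
  )
}

# Per-class amplitude profile on the half-spectrum frequency grid.
# Neutral shape: power ~ 1/f inside 1-40 Hz plus a flat broadband floor over
# 0.5-50 Hz; class band factors multiply the in-band *power*.
band_amplitude_profile <- function(freqs, factors) {
  pow <- rep(0, length(freqs))
  in_bb <- freqs >= 0.5 & freqs <= 50
  pow[in_bb] <- 0.05                       # broadband floor
  for (i in seq_len(nrow(EEG_BANDS))) {
    b <- EEG_BANDS[i, ]
    fac <- if (b$name %in% names(factors)) factors[[b$name]] else 1
    sel <- freqs >= b$lo & freqs < b$hi
    pow[sel] <- pow[sel] + fac / pmax(freqs[sel], 1)
  }
  sqrt(pow)
}

# Zero-mean random signals with the given half-spectrum amplitude profile
# (Fourier-domain brick-wall band shaping of Gaussian white noise); one
# signal per column, synthesized in a single batched inverse FFT.
synth_band_noise_mat <- function(n, amp_half, n_signals) {
  nh <- length(amp_half)            # n %/% 2 + 1 bins, DC..Nyquist
  re <- matrix(rnorm(nh * n_signals), nh) * amp_half
  im <- matrix(rnorm(nh * n_signals), nh) * amp_half
  re[1, ] <- 0; im[1, ] <- 0        # no DC
  if (n %% 2 == 0) im[nh, ] <- 0    # real Nyquist bin
  half <- matrix(complex(real = re, imaginary = im), nh)
  mirror <- (nh - 1 + (n %% 2)):2   # even n: bins nh-1..2; odd n: nh..2
  full <- rbind(half, Conj(half[mirror, , drop = FALSE]))
  Re(stats::mvfft(full, inverse = TRUE)) / sqrt(n)
}

synth_band_noise <- function(n, amp_half)
  synth_band_noise_mat(n, amp_half, 1)[, 1]

#' Generate one synthetic EEG recording
#'
#' Per channel, the signal is band-shaped Gaussian noise: a 1/f-like spectral
#' profile over 0.5-50 Hz whose per-band power is multiplied by the class's
#' planted factors, plus a shared common-source term mixed into every scalp
#' channel with weight 0.3 (so common-average referencing is non-trivial).
#' Deterministic given `(spec$seed, subject_id)`.
#'
#' @param spec A [cohort_spec()].
#' @param class_label One of `spec$classes`.
#' @param subject_id Integer subject index within the class.
#' @return An [eeg_recording()] with TUH-style channel labels
#'   (`"EEG FP1-REF"`, ...) and a `truth` record.
#' @export
generate_recording <- function(spec, class_label, subject_id) {
  if (!class_label %in% spec$classes)
    stop("unknown class label: ", class_label)
  cls_idx <- match(class_label, c("dilantin", "keppra", "none"))
  rec_seed <- mix_seed(spec$seed, cls_idx * 1000003 + subject_id)
  set.seed(rec_seed)

  n <- max(1L, as.integer(round(spec$duration * spec$sampling_rate)))
  freqs <- (seq_len(n %/% 2 + 1) - 1) * spec$sampling_rate / n
  factors <- spec$effect[[class_label]] %||% numeric(0)
  amp <- band_amplitude_profile(freqs, as.list(factors))
  amp_neutral <- band_amplitude_profile(freqs, list())

  # deterministic scale from the neutral profile -> target RMS ~ 20 uV;
  # class factors then shift realized band power, not the overall calibration
  v_neutral <- 2 * sum(amp_neutral^2) / n
  scale <- if (v_neutral > 0) 20 / sqrt(v_neutral) else 1

  chans <- CANONICAL_CHANNELS
  if (!is.null(spec$drop_channel))
    chans <- setdiff(chans, spec$drop_channel)

  sigs <- synth_band_noise_mat(n, amp, length(chans) + 1)
  common <- sigs[, 1]
  data <- scale * t(sigs[, -1, drop = FALSE] + 0.3 * common)

  labels <- sprintf("EEG %s-REF", toupper(chans))
  if (spec$distractors) {
    dist <- synth_band_noise_mat(n, amp_neutral, 3)
    extra <- rbind(scale * (dist[, 1] + 0.3 * common),
                   scale * (dist[, 2] + 0.3 * common),
                   500 * dist[, 3])
    data <- rbind(data, extra)
    labels <- c(labels, "EEG A1-REF", "EEG A2-REF", "EKG")
  }

  eeg_recording(
    data, labels, spec$sampling_rate,
    truth = list(class = class_label, subject_id = subject_id,
                 effect = factors, seed = rec_seed),
    id = sprintf("%s_%03d", class_label, subject_id)
  )
}

#' Generate clinical-style report text
#'
#' Produces a minimal fixed-grammar report with `MEDICATIONS:` and
#' `IMPRESSION:` lines plus age/sex lines, parseable by the report-labeling
#' module. The class `"poly"` lists two distinct medications (and is later
#' excluded by the polypharmacy rule).
#'
#' @param class_label One of `"dilantin"`, `"keppra"`, `"none"`, `"poly"`.
#' @param pathology `"normal"` or `"abnormal"`.
#' @param demographics Optional list with `age` (years) and `sex`
#'   (`"male"`/`"female"`); sampled from the current RNG stream if absent.
#' @return A single character string (the report).
#' @export
generate_report <- function(class_label, pathology = "abnormal",
                            demographics = NULL) {
  class_label <- match.arg(class_label,
                           c("dilantin", "keppra", "none", "poly"))
  pathology <- match.arg(pathology, c("normal", "abnormal"))
  age <- demographics$age %||% sample(18:90, 1)
  sex <- demographics$sex %||% sample(c("male", "female"), 1)
  meds <- switch(class_label,
    dilantin = sample(c("Dilantin", "phenytoin"), 1),
    keppra   = sample(c("Keppra", "levetiracetam"), 1),
    none     = "none",
    poly     = paste(sample(c("Dilantin", "Keppra", "Depakote",
                              "Tegretol", "Lamictal"), 2), collapse = ", ")
  )
  paste(
    sprintf("CLINICAL HISTORY: %d year old %s referred for routine EEG.",
            age, sex),
    sprintf("AGE: %d", age),
    sprintf("SEX: %s", sex),
    sprintf("MEDICATIONS: %s", meds),
    "INTRODUCTION: Digital EEG was recorded using the standard 10-20 system.",
    sprintf("IMPRESSION: %s EEG.", pathology),
    sep = "\n"
  )
}

#' Generate a full synthetic cohort
#'
#' `n_per_class` recordings per class, each paired with report text.
#' Deterministic under `spec$seed`. Optionally writes EDF files with `.txt`
#' sidecar reports and a JSON manifest to `out_dir`.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Optional directory; when given, each recording is written
#'   as `<id>.edf` + `<id>.txt` plus `manifest.json`.
#' @return A list of entries `list(recording, report, id, class)`.
#' @export
generate_cohort <- function(spec, out_dir = NULL) {
  out <- list()
  for (cl in spec$classes) {
    cls_idx <- match(cl, c("dilantin", "keppra", "none"))
    for (sid in seq_len(spec$n_per_class)) {
      rec <- generate_recording(spec, cl, sid)
      set.seed(mix_seed(spec$seed, 7 * (cls_idx * 1000003 + sid) + 3))
      rep_txt <- generate_report(cl, spec$pathology)
      out[[length(out) + 1]] <- list(recording = rec, report = rep_txt,
                                     id = rec$id, class = cl)
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (e in out) {
      write_edf(e$recording, file.path(out_dir, paste0(e$id, ".edf")))
      writeLines(e$report, file.path(out_dir, paste0(e$id, ".txt")))
    }
    manifest <- data.frame(
      id = vapply(out, `[[`, "", "id"),
      class = vapply(out, `[[`, "", "class"),
      fs = spec$sampling_rate, duration = spec$duration,
      pathology = spec$pathology
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         dataframe = "rows", auto_unbox = TRUE)
  }
  out
}
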