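#' @name preprocess
#' @title Canonicalize raw recordings into fixed-shape analysis segments
#'
#' @description
#' Every usable recording becomes a 19 x 30,000 segment at 100 Hz: channel
#' selection into the canonical 10-20 order, cropping to seconds [60, 360),
#' polyphase down-sampling to 100 Hz, zero-phase 0.5-50 Hz filtering, and
#' common average referencing. Recordings that cannot be canonicalized
#' (missing channels, shorter than 6 min, sub-100-Hz rate) are rejected
#' totally: [preprocess_recording()] returns an `omitted_recording` object
#' carrying the reason instead of a segment.
NULL

omission <- function(reason, id = NULL, missing = NULL) {
  stop(structure(
    class = c("omission_error", "error", "condition"),
    list(message = reason, call = NULL, id = id, missing = missing)
  ))
}

omitted_recording <- function(reason, id = NULL, missing = NULL) {
  structure(list(reason = reason, id = id, missing = missing),
            class = "omitted_recording")
}

#' Test whether a pipeline result is an omitted recording
#' @param x Object returned by [preprocess_recording()].
#' @return `TRUE` for `omitted_recording` objects.
#' @export
is_omitted <- function(x) inherits(x, "omitted_recording")

#' @export
print.omitted_recording <- function(x, ...) {
  cat(sprintf("<omitted recording%s: %s>\n",
              if (!is.null(x$id)) paste0(" ", x$id) else "", x$reason))
  invisible(x)
}

# TUH channel-label dialect -> canonical 10-20 name, or NA
normalize_channel_label <- function(label) {
  lab <- toupper(trimws(label))
  lab <- sub("^EEG\\s+", "", lab)
  lab <- sub("-(REF|LE)$", "", lab)
  idx <- match(lab, toupper(CANONICAL_CHANNELS))
  ifelse(is.na(idx), NA_character_, CANONICAL_CHANNELS[idx])
}

#' Restrict a recording to the 19 canonical channels in canonical order
#'
#' Label matching tolerates the TUH dialect: case-insensitive, with an
#' optional `"EEG "` prefix and `"-REF"`/`"-LE"` suffix. Distractor channels
#' (A1, A2, EKG, ...) are dropped silently; any *missing* canonical channel
#' makes the whole recording an omission.
#'
#' @param rec An [eeg_recording()].
#' @return The recording with exactly 19 channels in canonical order.
#' @export
select_channels <- function(rec) {
  canon <- normalize_channel_label(rec$channels)
  idx <- match(CANONICAL_CHANNELS, canon)
  if (anyNA(idx)) {
    miss <- CANONICAL_CHANNELS[is.na(idx)]
    omission(sprintf("missing channels: %s", paste(miss, collapse = ", ")),
             id = rec$id, missing = miss)
  }
  eeg_recording(rec$data[idx, , drop = FALSE], CANONICAL_CHANNELS, rec$fs,
                truth = rec$truth, id = rec$id)
}

#' Crop a recording to seconds [60, 360)
#'
#' The first minute is discarded (settling artifacts) and exactly the next
#' five minutes retained (half-open sample window at the recording's own
#' sampling rate). Recordings shorter than 360 s are omissions.
#'
#' @param rec A channel-selected [eeg_recording()].
#' @return The cropped recording (300 s).
#' @export
crop_segment <- function(rec) {
  n <- ncol(rec$data)
  if (n < 360 * rec$fs)
    omission("shorter than 6 min", id = rec$id)
  keep <- (60 * rec$fs + 1):(360 * rec$fs)
  eeg_recording(rec$data[, keep, drop = FALSE], rec$channels, rec$fs,
                truth = rec$truth, id = rec$id)
}

#' Down-sample a recording to 100 Hz
#'
#' Anti-alias-filtered polyphase resampling at the rational ratio
#' `100 / fs` (so 256 Hz is handled exactly as 25/64). Rates below 100 Hz
#' are an error: up-sampling is not part of the procedure. The output is
#' trimmed/padded by at most one sample to exactly `round(duration * 100)`.
#'
#' @param rec A cropped [eeg_recording()].
#' @return The recording at 100 Hz.
#' @export
resample_100 <- function(rec) {
  if (rec$fs < 100) stop("cannot up-sample: fs < 100 Hz", call. = FALSE)
  n_out <- as.integer(round(ncol(rec$data) * 100 / rec$fs))
  if (rec$fs == 100) return(rec)
  g <- pracma_gcd(100L, as.integer(round(rec$fs)))
  p <- 100L %/% g; q <- as.integer(round(rec$fs)) %/% g
  data <- t(apply(rec$data, 1, function(x) {
    y <- signal::resample(x, p, q)
    length(y) <- n_out          # pads with NA if short
    y[is.na(y)] <- 0
    y
  }))
  eeg_recording(data, rec$channels, 100, truth = rec$truth, id = rec$id)
}

pracma_gcd <- function(a, b) if (b == 0) a else pracma_gcd(b, a %% b)

#' Zero-phase 0.5-50 Hz filtering and common average referencing
#'
#' A 4th-order Butterworth high-pass at 0.5 Hz is applied forward-backward
#' per channel (at 100 Hz the 50 Hz band edge coincides with Nyquist, so
#' the band-pass reduces to its high-pass branch); each sample is then
#' reduced by its cross-channel mean.
#'
#' @param rec A 19 x 30,000 recording at 100 Hz.
#' @return A `canonical_segment`: 19 x 30,000 matrix at 100 Hz whose
#'   cross-channel mean is ~0 at every sample.
#' @export
bandpass_car <- function(rec) {
  if (!all(is.finite(rec$data))) stop("non-finite input values", call. = FALSE)
  if (rec$fs != 100 || nrow(rec$data) != 19)
    stop("bandpass_car expects a 19-channel recording at 100 Hz", call. = FALSE)
  bf <- signal::butter(4, 0.5 / (rec$fs / 2), type = "high")
  filt <- .filtfilt_rows(bf$b, bf$a, rec$data)
  car <- sweep(filt, 2, colMeans(filt))
  structure(
    list(data = `rownames<-`(car, CANONICAL_CHANNELS), fs = 100,
         channel_order = CANONICAL_CHANNELS,
         provenance = list(id = rec$id, crop = "[60, 360) s",
                           filter = "butterworth order 4 high-pass 0.5 Hz, filtfilt",
                           reference = "common average"),
         truth = rec$truth, id = rec$id),
    class = "canonical_segment"
  )
}

#' @export
print.canonical_segment <- function(x, ...) {
  cat(sprintf("<canonical_segment%s: 19 x %d @ 100 Hz>\n",
              if (!is.null(x$id)) paste0(" ", x$id) else "", ncol(x$data)))
  invisible(x)
}

#' Full preprocessing chain
#'
#' Composition `select_channels` -> `crop_segment` -> `resample_100` ->
#' `bandpass_car`. Total: every input yields exactly one of a
#' `canonical_segment` or an `omitted_recording` with a reason.
#'
#' @param rec An [eeg_recording()].
#' @return A `canonical_segment`, or an `omitted_recording`.
#' @export
preprocess_recording <- function(rec) {
  tryCatch(
    bandpass_car(resample_100(crop_segment(select_channels(rec)))),
    omission_error = function(e)
      omitted_recording(conditionMessage(e), id = e$id, missing = e$missing)
  )
}

#' Preprocess a cohort
#'
#' Applies [preprocess_recording()] to every entry, returning the surviving
#' segments and logging omissions.
#'
#' @param cohort List of entries with `$recording` (or of recordings).
#' @param quiet Suppress the omission-count message.
#' @return List of `canonical_segment`s; omitted ids in attribute
#'   `"omitted"` (named by reason).
#' @export
preprocess_cohort <- function(cohort, quiet = FALSE) {
  segs <- list(); omitted <- character(0)
  for (e in cohort) {
    rec <- if (inherits(e, "eeg_recording")) e else e$recording
    res <- preprocess_recording(rec)
    if (is_omitted(res)) {
      omitted[as.character(res$id %||% (length(omitted) + 1))] <- res$reason
    } else {
      segs[[length(segs) + 1]] <- res
    }
  }
  if (!quiet && length(omitted) > 0)
    message(sprintf("preprocess_cohort: omitted %d recording(s)",
                    length(omitted)))
  attr(segs, "omitted") <- omitted
  segs
}
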