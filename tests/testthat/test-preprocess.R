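make_named_rec <- function(labels, n = 1000, fs = 100, fill = NULL) {
  set.seed(123)
  data <- fill %||% matrix(rnorm(length(labels) * n), length(labels), n)
  eeg_recording(data, labels, fs)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("channel selection tolerates the TUH label dialect and reorders", {
  labs <- c(sprintf("EEG %s-REF", toupper(rev(CANONICAL_CHANNELS))),
            "EEG A1-REF", "EKG")
  rec <- make_named_rec(labs)
  sel <- select_channels(rec)
  expect_equal(sel$channels, CANONICAL_CHANNELS)
  # reversed input: canonical channel i must carry the data of input 20-i
  expect_equal(sel$data[1, ], rec$data[19, ])
  expect_equal(sel$data[19, ], rec$data[1, ])
  # lowercase / -LE suffix dialect
  rec2 <- make_named_rec(sprintf("eeg %s-le", tolower(CANONICAL_CHANNELS)))
  expect_equal(select_channels(rec2)$channels, CANONICAL_CHANNELS)
})

test_that("a missing canonical channel is an omission naming the channel", {
  labs <- sprintf("EEG %s-REF", toupper(setdiff(CANONICAL_CHANNELS, "T5")))
  rec <- make_named_rec(labs)
  out <- preprocess_recording(rec)
  expect_true(is_omitted(out))
  expect_equal(out$missing, "T5")
  err <- tryCatch(select_channels(rec), omission_error = function(e) e)
  expect_s3_class(err, "omission_error")
})

test_that("cropping keeps exactly seconds [60, 360) at the native rate", {
  rec <- make_named_rec(sprintf("EEG %s-REF", toupper(CANONICAL_CHANNELS)),
                        n = 400 * 100)
  cr <- crop_segment(rec)
  expect_equal(ncol(cr$data), 30000)
  expect_equal(cr$data[1, 1], rec$data[1, 6001])       # half-open window
  expect_equal(cr$data[1, 30000], rec$data[1, 36000])
  # exact 360 s boundary is accepted
  rec2 <- make_named_rec(sprintf("EEG %s-REF", toupper(CANONICAL_CHANNELS)),
                         n = 360 * 100)
  expect_equal(ncol(crop_segment(rec2)$data), 30000)
  # 300 s is an omission
  rec3 <- make_named_rec(sprintf("EEG %s-REF", toupper(CANONICAL_CHANNELS)),
                         n = 300 * 100)
  err <- tryCatch(crop_segment(rec3), omission_error = function(e) e)
  expect_match(conditionMessage(err), "6 min")
})

test_that("down-sampling preserves tone frequency and sample counts", {
  # 250 Hz, 300 s -> 30,000 samples at 100 Hz
  rec <- eeg_recording(matrix(rnorm(2 * 75000), 2), c("a", "b"), 250)
  rs <- resample_100(rec)
  expect_equal(ncol(rs$data), 30000)
  expect_equal(rs$fs, 100)
  # already 100 Hz: identity
  rec2 <- eeg_recording(matrix(rnorm(500), 1), "a", 100)
  expect_identical(resample_100(rec2)$data, rec2$data)
  # sub-100-Hz input is an error, not an omission
  expect_error(resample_100(eeg_recording(matrix(0, 1, 50), "a", 50)),
               "up-sample")
  # 10 Hz tone at 500 Hz keeps its periodogram peak at 10 Hz
  t5 <- seq(0, 20 - 1 / 500, by = 1 / 500)
  tone <- sin(2 * pi * 10 * t5)
  rs3 <- resample_100(eeg_recording(matrix(tone, 1), "a", 500))
  psd <- periodogram(rs3$data[1, ], 100)
  peak <- psd$freqs[which.max(psd$power)]
  expect_lt(abs(peak - 10), 100 / length(rs3$data[1, ]) + 1e-9)
  # 256 Hz (non-integer ratio) resolves through the rational polyphase path
  rec4 <- eeg_recording(matrix(rnorm(256 * 30), 1), "a", 256)
  expect_equal(ncol(resample_100(rec4)$data), 3000)
})

test_that("filtering plus CAR yields zero cross-channel mean and kills drift", {
  set.seed(42)
  rec <- eeg_recording(matrix(rnorm(19 * 30000), 19),
                       CANONICAL_CHANNELS, 100)
  seg <- bandpass_car(rec)
  rms <- sqrt(mean(seg$data^2))
  expect_lt(max(abs(colMeans(seg$data))), 1e-9 * rms)
  # identical channels: CAR removes everything
  one <- matrix(rep(rnorm(30000), each = 19), 19)
  seg2 <- bandpass_car(eeg_recording(one, CANONICAL_CHANNELS, 100))
  expect_lt(max(abs(seg2$data)), 1e-9)
  # high-pass response: >= 20 dB down at 0.05 Hz, flat at 10 Hz
  bf <- signal::butter(4, 0.5 / 50, type = "high")
  h <- function(f) {
    z <- exp(-1i * 2 * pi * f / 100)
    Mod(sum(bf$b * z^(0:(length(bf$b) - 1))) /
          sum(bf$a * z^(0:(length(bf$a) - 1))))^2   # squared: zero-phase
  }
  expect_lt(10 * log10(h(0.05) / h(10)), -20)
  # non-finite input is an error
  bad <- rec; bad$data[1, 1] <- NA
  expect_error(bandpass_car(bad), "finite")
})

test_that("the full chain produces canonical segments deterministically", {
  spec <- cohort_spec(1, classes = "none", duration = 420,
                      sampling_rate = 250, seed = 3, distractors = TRUE)
  rec <- generate_recording(spec, "none", 1)
  seg <- preprocess_recording(rec)
  expect_s3_class(seg, "canonical_segment")
  expect_equal(dim(seg$data), c(19, 30000))
  expect_equal(seg$channel_order, CANONICAL_CHANNELS)
  expect_equal(seg$fs, 100)
  seg2 <- preprocess_recording(rec)
  expect_identical(seg$data, seg2$data)
  # energy bound: filtering + CAR are non-amplifying up to ripple
  in_rms <- sqrt(mean(select_channels(rec)$data^2))
  expect_lt(sqrt(mean(seg$data^2)), in_rms * 1.1)
})

test_that("omission is total over a mixed cohort", {
  ok <- cohort_spec(1, classes = "none", seed = 1)
  bad <- cohort_spec(1, classes = "none", duration = 100, seed = 2)
  coh <- c(generate_cohort(ok), generate_cohort(bad))
  segs <- preprocess_cohort(coh, quiet = TRUE)
  expect_length(segs, 1)
  expect_length(attr(segs, "omitted"), 1)
})
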