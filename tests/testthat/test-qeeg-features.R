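test_that("periodogram satisfies Parseval and localizes pure tones", {
  set.seed(10)
  x <- rnorm(4096)
  psd <- periodogram(x, 100)
  expect_true(all(psd$power >= 0))
  expect_equal(sum(psd$power), var(x) * (4095 / 4096), tolerance = 0.05)
  expect_equal(max(psd$freqs), 50)
  # 10 Hz unit sine: single dominant bin holding >= 99% of total power
  t <- (0:2999) / 100
  ps <- periodogram(sin(2 * pi * 10 * t), 100)
  expect_gte(max(ps$power) / sum(ps$power), 0.99)
  expect_equal(ps$freqs[which.max(ps$power)], 10)
  # zero signal -> all-zero power
  expect_true(all(periodogram(rep(0, 64), 100)$power == 0))
  expect_error(periodogram(c(1, NA, 3), 100), "finite")
})

test_that("band powers split the spectrum correctly", {
  t <- (0:2999) / 100
  psd <- periodogram(sin(2 * pi * 10 * t), 100)
  bp <- band_powers(psd)
  expect_gte(bp[["rel_alpha"]], 0.99)
  expect_true(all(bp[paste0("rel_", setdiff(EEG_BANDS$name, "alpha"))] <=
                    0.01))
  # white noise: relative powers proportional to bandwidth within 0.02
  set.seed(11)
  bpw <- band_powers(periodogram(rnorm(30000), 100))
  widths <- EEG_BANDS$hi - EEG_BANDS$lo
  expect_true(all(abs(bpw[paste0("rel_", EEG_BANDS$name)] - widths / 50)
                  < 0.02))
  # zero-signal guard
  expect_true(all(band_powers(periodogram(rep(0, 64), 100)) == 0))
  # relative powers live in [0,1] and sum below 1 (bands cover 1-40 Hz)
  rel <- bpw[paste0("rel_", EEG_BANDS$name)]
  expect_true(all(rel >= 0 & rel <= 1))
  expect_lte(sum(rel), 1)
})

test_that("spectral entropies obey the closed forms", {
  flat <- structure(list(freqs = 0:9, power = rep(0.2, 10)),
                    class = "periodogram")
  expect_equal(spectral_entropies(flat)[["spec_entropy_norm"]], log(10))
  single <- structure(list(freqs = 0:9, power = c(5, rep(0, 9))),
                      class = "periodogram")
  expect_equal(spectral_entropies(single)[["spec_entropy_norm"]], 0)
  two <- structure(list(freqs = 0:3, power = c(3, 3, 0, 0)),
                   class = "periodogram")
  expect_equal(spectral_entropies(two)[["spec_entropy_norm"]], log(2))
  # raw entropy differs from normalized unless the PSD already sums to 1
  expect_equal(spectral_entropies(flat)[["spec_entropy_raw"]],
               -10 * 0.2 * log(0.2))
  zero <- structure(list(freqs = 0:3, power = rep(0, 4)),
                    class = "periodogram")
  expect_equal(unname(spectral_entropies(zero)), c(0, 0))
})

test_that("time-domain features match closed forms on simple signals", {
  N <- 100
  ramp <- as.numeric(0:(N - 1))
  tf <- time_features(ramp, 100)
  expect_equal(tf[["curve_length"]], N - 1)
  expect_equal(tf[["median"]], (N - 1) / 2)
  expect_equal(tf[["integral"]], sum(ramp) / 100)
  expect_equal(tf[["min"]], 0)
  expect_equal(tf[["max"]], N - 1)
  # constant signal: guarded degenerate values
  cf <- time_features(rep(3, 50), 100)
  expect_equal(unname(cf[c("nonlinear_energy", "variance", "mobility",
                           "complexity", "skew", "kurtosis",
                           "signal_entropy")]),
               rep(0, 7))
  expect_error(time_features(c(1, Inf, 2), 100), "finite")
})

test_that("LZ76 reproduces the hand-parsed example and its invariances", {
  s <- as.integer(strsplit("0001101001000101", "")[[1]])
  expect_equal(eegmedstate:::.lz76_count(s), 6)
  # constant and alternating sequences
  expect_equal(eegmedstate:::.lz76_count(rep(0L, 20)), 2)
  set.seed(12)
  x <- rnorm(500)
  # invariant under positive affine transforms (threshold is the mean)
  expect_equal(lempel_ziv_complexity(x), lempel_ziv_complexity(3 * x + 7))
  # agreement with the exhaustive-history scan oracle
  for (i in 1:60) {
    s <- sample(0:1, sample(2:120, 1), replace = TRUE)
    expect_equal(eegmedstate:::.lz76_count(s), oracle_lz76(s))
  }
})

test_that("Hjorth mobility of white noise approaches sqrt(2)", {
  set.seed(13)
  tf <- time_features(rnorm(30000), 100)
  expect_equal(tf[["mobility"]], sqrt(2), tolerance = 0.05 / sqrt(2))
})

test_that("the battery yields 570 named finite features in canonical order", {
  seg <- fixture_segment()
  fv <- feature_vector(seg)
  expect_length(fv, 570)
  expect_true(all(is.finite(fv)))
  expect_equal(names(fv), qeeg_feature_names())
  expect_equal(names(fv)[1], "Fp1__abs_delta")
  expect_equal(names(fv)[570], "Pz__complexity")
  # 31-feature variant with the redundant sum re-enabled
  fv31 <- feature_vector(seg, include_sum = TRUE)
  expect_length(fv31, 589)
  expect_equal(fv31[["C3__sum"]], fv31[["C3__integral"]] * 100)
})

test_that("feature blocks are pure per channel and scale as documented", {
  set.seed(14)
  base <- rnorm(2000)
  seg <- make_mini_segment(rbind(base, base, 2 * base))
  fv <- feature_vector(seg)
  b1 <- fv[1:30]; b2 <- fv[31:60]; b3 <- fv[61:90]
  expect_equal(unname(b1), unname(b2))          # identical inputs
  expect_equal(b3[["ch3__energy"]], 4 * b1[["ch1__energy"]])
  expect_equal(b3[["ch3__rel_alpha"]], b1[["ch1__rel_alpha"]])
  expect_equal(b3[["ch3__lzc"]], b1[["ch1__lzc"]])
})

test_that("every feature matches its naive-loop oracle to 1e-9", {
  set.seed(15)
  for (i in 1:10) {
    x <- rnorm(512) * runif(1, 0.5, 20)
    seg <- make_mini_segment(matrix(x, 1))
    got <- feature_vector(seg)
    want <- oracle_channel_features(x, 100, EEG_BANDS)
    expect_rel_equal(unname(got), unname(want))
  }
})

test_that("the feature registry documents all thirty features", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 30)
  expect_true(all(nzchar(reg$definition)))
  expect_setequal(paste0("Fp1__", reg$feature),
                  qeeg_feature_names()[1:30])
})
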