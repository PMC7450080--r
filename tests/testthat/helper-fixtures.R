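# Shared fixtures, memoized so expensive synthetic cohorts are built once
# per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, build(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# a single canonical segment from the default generator
fixture_segment <- function() memo("segment", function() {
  spec <- cohort_spec(n_per_class = 1, classes = "none", seed = 400)
  preprocess_recording(generate_recording(spec, "none", 1))
})

# small matrix posing as a short multichannel segment for feature tests
make_mini_segment <- function(data, fs = 100) {
  rownames(data) <- paste0("ch", seq_len(nrow(data)))
  list(data = data, fs = fs)
}

# alpha-effect cohort features: dilantin alpha x0.5 vs none, 50 per class
fixture_alpha_features <- function() memo("alpha_fm", function() {
  spec <- cohort_spec(n_per_class = 50, classes = c("dilantin", "none"),
                      effect = list(dilantin = c(alpha = 0.5)), seed = 501)
  cohort_feature_matrix(spec)
})

# single-class cohort with boosted alpha, for the monotonicity check
fixture_alpha_hi_features <- function() memo("alpha_hi_fm", function() {
  spec <- cohort_spec(n_per_class = 50, classes = "dilantin",
                      effect = list(dilantin = c(alpha = 1.5)), seed = 502)
  cohort_feature_matrix(spec)
})

mean_abs_alpha <- function(fm, cls) {
  cols <- grep("__abs_alpha$", colnames(fm$x))
  mean(fm$x[fm$labels == cls, cols])
}
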