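published_abnormal_table <- function() {
  # recording counts by medication class in the abnormal-EEG stratum
  data.frame(
    recording_id = sprintf("r%05d", 1:(320 + 264 + 1285)),
    medication_class = rep(c("dilantin", "keppra", "none"),
                           c(320, 264, 1285)),
    eeg_status = "abnormal",
    stringsAsFactors = FALSE
  )
}

test_that("balancing reproduces the published task sizes", {
  tab <- published_abnormal_table()
  dn <- balance_classes(tab, "dilantin", "none", "abnormal", seed = 1)
  expect_equal(nrow(dn), 640)
  expect_equal(as.integer(table(dn$medication_class)), c(320, 320))
  kn <- balance_classes(tab, "keppra", "none", "abnormal", seed = 1)
  expect_equal(nrow(kn), 528)
  dk <- balance_classes(tab, "dilantin", "keppra", "abnormal", seed = 1)
  expect_equal(nrow(dk), 528)
  # already-equal classes pass through unchanged
  eq <- tab[tab$medication_class != "none", ]
  eq <- eq[c(1:264, 321:584), ]
  bal <- balance_classes(eq, "dilantin", "keppra", "abnormal", seed = 2)
  expect_setequal(bal$recording_id, eq$recording_id)
  expect_error(balance_classes(tab[0, ], "dilantin", "none"), "dilantin")
})

test_that("repeated splits are disjoint, exhaustive, stratified and seeded", {
  y <- rep(c("a", "b"), each = 320)
  sp <- repeated_splits(y, n_reps = 10, seed = 4)
  expect_length(sp, 10)
  for (s in sp) {
    expect_length(s$test, 64)                    # floor(0.1 * 640)
    expect_length(intersect(s$train, s$test), 0)
    expect_setequal(c(s$train, s$test), seq_along(y))
    expect_equal(as.integer(table(y[s$test])), c(32, 32))
  }
  # distinct repetitions, reproducible under the seed
  expect_false(identical(sp[[1]]$test, sp[[2]]$test))
  expect_identical(sp, repeated_splits(y, n_reps = 10, seed = 4))
  y2 <- rep(c("a", "b"), each = 264)
  expect_length(repeated_splits(y2, seed = 1)[[1]]$test, 52)
  expect_error(repeated_splits(rep(c("a", "b"), 5)), "at least 20")
})

test_that("the hand Kruskal-Wallis matches closed forms and invariances", {
  kw <- kruskal_wallis(c(1, 2, 3), c(4, 5, 6))
  expect_equal(kw$H, 27 / 7, tolerance = 1e-12)
  expect_equal(kw$p, pchisq(27 / 7, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  # identical vectors: guard
  same <- kruskal_wallis(rep(0.7, 5), rep(0.7, 5))
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)
  expect_equal(same$tier, "ns")
  # rank invariance under monotone transforms
  a <- c(0.61, 0.55, 0.72, 0.66); b <- c(0.48, 0.52, 0.50, 0.57)
  expect_equal(kruskal_wallis(a, b)$H, kruskal_wallis(100 * a, 100 * b)$H)
  expect_equal(kruskal_wallis(a, b)$H, kruskal_wallis(exp(a), exp(b))$H)
})

test_that("the statistic agrees with the rank oracle and stats::kruskal.test", {
  set.seed(30)
  for (i in 1:100) {
    na <- sample(2:8, 1); nb <- sample(2:8, 1)
    # discrete values force ties, the hard case for the correction
    a <- sample(seq(0, 1, by = 0.1), na, replace = TRUE)
    b <- sample(seq(0, 1, by = 0.1), nb, replace = TRUE)
    if (length(unique(c(a, b))) == 1) next
    kw <- kruskal_wallis(a, b)
    expect_equal(kw$H, oracle_kruskal_H(a, b), tolerance = 1e-9)
    ref <- stats::kruskal.test(list(a, b))
    expect_equal(kw$H, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(kw$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("significance tiers honor the thresholds exactly", {
  expect_equal(eegmedstate:::significance_tier(0.009), "*")
  expect_equal(eegmedstate:::significance_tier(0.011), "ns")
  expect_equal(eegmedstate:::significance_tier(0.0009), "**")
  expect_equal(eegmedstate:::significance_tier(0.001), "*")
  expect_equal(eegmedstate:::significance_tier(0.01), "ns")
  # non-overlapping accuracy vectors: minimal attainable p for 10 + 10
  set.seed(31)
  correct <- structure(list(accuracies = 0.7 + runif(10, 0, 0.01)),
                       class = "cv_result")
  null <- structure(list(accuracies = 0.5 + runif(10, 0, 0.01)),
                    class = "cv_result")
  rep <- significance_report(correct, null)
  expect_equal(rep$tier, "**")
  expect_equal(rep$H, oracle_kruskal_H(correct$accuracies,
                                       null$accuracies), tolerance = 1e-9)
  same <- significance_report(correct, correct)
  expect_equal(same$tier, "ns")
})

test_that("run_protocol fits on train only and is fully reproducible", {
  set.seed(33)
  x <- matrix(rnorm(60 * 12), 60, 12,
              dimnames = list(NULL, paste0("f", 1:12)))
  y <- rep(c("a", "b"), each = 30)
  x[y == "b", 3] <- x[y == "b", 3] + 6
  cv <- run_protocol(x, y, "rf", seed = 40)
  expect_s3_class(cv, "cv_result")
  expect_length(cv$accuracies, 10)
  expect_true(all(cv$accuracies >= 0 & cv$accuracies <= 1))
  expect_equal(cv$n_total, 60)
  expect_equal(cv$n_test, 6)
  expect_gt(mean(cv$accuracies), 0.9)            # separable planted feature
  cv2 <- run_protocol(x, y, "rf", seed = 40)
  expect_identical(cv$accuracies, cv2$accuracies)
  # label-free features: chance level
  set.seed(34)
  x0 <- matrix(rnorm(60 * 12), 60, 12,
               dimnames = list(NULL, paste0("f", 1:12)))
  cv0 <- run_protocol(x0, y, "rf", seed = 41)
  expect_lt(abs(mean(cv0$accuracies) - 0.5), 0.2)
})

test_that("the random-label null destroys a real association", {
  set.seed(35)
  x <- matrix(rnorm(60 * 8), 60, 8,
              dimnames = list(NULL, paste0("f", 1:8)))
  y <- rep(c("a", "b"), each = 30)
  x[y == "b", 1] <- x[y == "b", 1] + 6
  nul <- random_label_null(x, y, "rf", seed = 50)
  expect_true(nul$random_labels)
  expect_lt(abs(mean(nul$accuracies) - 0.5), 0.2)
  expect_identical(nul$accuracies,
                   random_label_null(x, y, "rf", seed = 50)$accuracies)
  cor <- run_protocol(x, y, "rf", seed = 50)
  expect_gt(mean(cor$accuracies) - mean(nul$accuracies), 0.3)
  rep <- significance_report(cor, nul)
  expect_true(rep$tier %in% c("*", "**"))
})

test_that("pairwise comparison tables cover every pair", {
  res <- list(m1 = c(0.7, 0.72, 0.71), m2 = c(0.5, 0.52, 0.51),
              m3 = c(0.71, 0.69, 0.7))
  tab <- compare_cv_results(res)
  expect_equal(nrow(tab), 3)
  expect_setequal(paste(tab$a, tab$b),
                  c("m1 m2", "m1 m3", "m2 m3"))
  expect_true(all(tab$H >= 0))
})
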