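# small input shapes (with adapted kernels/pools) keep training tests fast;
# the canonical 19 x 30000 builds are exercised for weight accounting

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_opts <- list(
  scnn = list(n_filters = 6, kernel_time = 5, pool = 4),
  dcnn = list(n_filters = c(4, 6, 8, 10), kernels = c(5, 3, 3, 3),
              pools = c(2, 2, 2, 2)),
  eegnet = list(F1 = 4, kernel_time = 8, D = 2, pool1 = 2,
                kernel_sep = 4, pool2 = 2)
)

rand_segments <- function(n, ch = 4, len = 40, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) matrix(rnorm(ch * len), ch, len))
}

test_that("weight accounting reproduces the printed totals", {
  expect_equal(count_weights(build_network("lnn")), 2 * 19 * 30000)
  expect_equal(count_weights(build_network("scnn")), 38162)
  expect_equal(count_weights(build_network("dcnn")), 279927)
  expect_equal(count_weights(build_network("eegnet")), 13296)
  # closed form: a bias-free dense layer counts d_in x d_out
  lnn <- build_network("lnn", input_shape = c(3, 7), n_classes = 2)
  expect_equal(count_weights(lnn), 3 * 7 * 2)
  expect_error(build_network("mlp"), "arg")
})

test_that("the architecture registry reports layer shapes and subtotals", {
  net <- build_network("scnn")
  reg <- network_registry(net)
  expect_equal(sum(reg$n_params), 38162)
  expect_equal(reg$layer[1:2], c("conv_time", "conv_spat"))
  # temporal-then-spatial split: first conv keeps 19 channels, second
  # collapses them
  expect_match(reg$out_shape[1], "^40x19x")
  expect_match(reg$out_shape[2], "^40x1x")
  dr <- network_registry(build_network("dcnn"))
  expect_equal(sum(dr$n_params), 279927)
  expect_equal(sum(dr$layer == "conv_map"), 3)  # three further conv-pool pairs
})

test_that("softmax outputs normalize and untrained accuracy is chance-level", {
  segs <- rand_segments(40, ch = 6, len = 50, seed = 8)
  net <- build_network("lnn", input_shape = c(6, 50), seed = 21)
  probs <- network_predict_proba(net, segs)
  expect_equal(colSums(probs), rep(1, 40), tolerance = 1e-6)
  y <- rep(c("a", "b"), 20)
  acc <- network_predict_accuracy(net, segs, y)
  expect_lt(abs(acc - 0.5), 0.15 + 1e-9)
})

test_that("analytic gradients match numerical gradients for every layer", {
  for (arch in c("lnn", "scnn", "dcnn", "eegnet")) {
    shape <- if (arch == "dcnn") c(4, 80) else c(4, 40)
    net <- build_network(arch, input_shape = shape, seed = 3,
                         opts = tiny_opts[[arch]] %||% list())
    for (i in seq_along(net$layers))
      if (net$layers[[i]]$type == "dropout") net$layers[[i]]$p <- 0
    set.seed(9)
    x <- array(rnorm(shape[1] * shape[2] * 4), c(1, shape[1], shape[2], 4))
    y <- rep(1:2, 2)
    lg <- eegmedstate:::nn_loss_grads(net, x, y, training = TRUE)
    worst <- 0
    for (li in seq_along(net$layers)) {
      for (nm in names(net$layers[[li]]$params)) {
        P <- net$layers[[li]]$params[[nm]]
        for (ix in sample(length(P), min(3, length(P)))) {
          eps <- 1e-5
          n2 <- net
          n2$layers[[li]]$params[[nm]][ix] <- P[ix] + eps
          lp <- eegmedstate:::nn_loss_grads(n2, x, y, training = TRUE)$loss
          n2$layers[[li]]$params[[nm]][ix] <- P[ix] - eps
          lm <- eegmedstate:::nn_loss_grads(n2, x, y, training = TRUE)$loss
          num <- (lp - lm) / (2 * eps)
          ana <- lg$grads[[li]][[nm]][ix]
          worst <- max(worst, abs(num - ana) /
                         max(1e-6, abs(num) + abs(ana)))
        }
      }
    }
    expect_lt(worst, 1e-4)
  }
})

test_that("one Adam step on a batch decreases that batch's loss", {
  for (arch in c("lnn", "scnn", "dcnn", "eegnet")) {
    shape <- if (arch == "dcnn") c(4, 80) else c(4, 40)
    net <- build_network(arch, input_shape = shape, seed = 5,
                         opts = tiny_opts[[arch]] %||% list())
    for (i in seq_along(net$layers))
      if (net$layers[[i]]$type == "dropout") net$layers[[i]]$p <- 0
    set.seed(10)
    x <- array(rnorm(shape[1] * shape[2] * 8), c(1, shape[1], shape[2], 8))
    y <- rep(1:2, 4)
    lg <- eegmedstate:::nn_loss_grads(net, x, y, training = TRUE)
    st <- eegmedstate:::adam_init(net)
    up <- eegmedstate:::adam_step(lg$net, lg$grads, st, 1, lr = 1e-3)
    l2 <- eegmedstate:::nn_loss_grads(up$net, x, y, training = TRUE)$loss
    expect_lt(l2, lg$loss)
  }
})

test_that("the two-run protocol records run 1 fully and stops run 2 on target", {
  segs <- rand_segments(30, ch = 4, len = 40, seed = 11)
  y <- rep(c("a", "b"), 15)
  net <- build_network("scnn", input_shape = c(4, 40), seed = 7,
                       opts = tiny_opts$scnn)
  tr <- suppressWarnings(
    train_two_run(net, segs, y, list(run1_epochs = 6, batch_size = 8,
                                     seed = 13)))
  expect_equal(nrow(tr$run1), 6)
  expect_equal(tr$best_epoch,
               which.max(tr$run1$train_accuracy))
  expect_equal(tr$target_loss, tr$run1$train_loss[tr$best_epoch])
  final2 <- tail(tr$run2$train_loss, 1)
  expect_true(final2 <= tr$target_loss || nrow(tr$run2) == 6)
  # determinism: identical seeds give identical run-1 trajectories
  tr2 <- suppressWarnings(
    train_two_run(build_network("scnn", input_shape = c(4, 40), seed = 7,
                                opts = tiny_opts$scnn),
                  segs, y, list(run1_epochs = 6, batch_size = 8, seed = 13)))
  expect_identical(tr$run1$train_loss, tr2$run1$train_loss)
  # shape mismatch is an error
  expect_error(train_two_run(net, rand_segments(4, ch = 3, len = 40),
                             rep(c("a", "b"), 2)), "shape")
})

test_that("networks run under the ten-split protocol from raw segments", {
  segs <- rand_segments(24, ch = 4, len = 40, seed = 17)
  y <- rep(c("a", "b"), 12)
  cv <- suppressWarnings(
    run_protocol(segs, y, "lnn", seed = 19, n_reps = 3,
                 network_config = list(run1_epochs = 2, batch_size = 8)))
  expect_length(cv$accuracies, 3)
  expect_true(all(cv$accuracies >= 0 & cv$accuracies <= 1))
  expect_equal(cv$n_test, 2)
  cv2 <- suppressWarnings(
    run_protocol(segs, y, "lnn", seed = 19, n_reps = 3,
                 network_config = list(run1_epochs = 2, batch_size = 8)))
  expect_identical(cv$accuracies, cv2$accuracies)
})

test_that("a band-power contrast is learnable by the shallow ConvNet", {
  # class "hi" carries a strong 10 Hz rhythm; the square -> mean-pool ->
  # log stage is exactly the matched statistic
  set.seed(14)
  mk <- function(amp, n) lapply(seq_len(n), function(i) {
    t <- (0:399) / 100
    ph <- runif(4, 0, 2 * pi)
    base <- matrix(rnorm(4 * 400, sd = 1), 4, 400)
    base + amp * sin(outer(rep(1, 4) * 2 * pi * 10, t) + ph)
  })
  segs <- c(mk(2, 30), mk(0.3, 30))
  y <- rep(c("hi", "lo"), each = 30)
  net <- build_network("scnn", input_shape = c(4, 400), seed = 15,
                       opts = list(n_filters = 8, kernel_time = 11,
                                   pool = 40))
  tr <- suppressWarnings(
    train_two_run(net, segs, y, list(run1_epochs = 10, batch_size = 10,
                                     lr = 3e-3, seed = 16)))
  expect_gt(network_predict_accuracy(tr, segs, y), 0.6)
})
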