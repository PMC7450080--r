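#' @name network_models
#' @title Raw-EEG network architectures with exact weight accounting
#'
#' @description
#' Four feed-forward architectures operating on the canonical 19 x 30,000
#' input (channels x time, canonical channel order): a linear network
#' (LNN), a shallow ConvNet (SCNN) whose temporal-then-spatial split
#' convolution followed by squaring, mean pooling and a log activation
#' mirrors the log-variance step of filter-bank common spatial patterns, a
#' deep ConvNet (DCNN) with three further conv-pool pairs, and EEGNet with
#' depthwise and separable convolutions. Trainable-weight accounting:
#' convolution biases are omitted wherever batch normalization follows;
#' batch-norm affine pairs count; the classifier layer carries a bias in
#' the SCNN and DCNN and none in the LNN and EEGNet. With the canonical
#' input this yields 1,140,000 (LNN), 38,162 (SCNN), 279,927 (DCNN) and
#' 13,296 (EEGNet) trainable weights. Kernel and pooling lengths that the
#' architecture sketches leave open were fixed so that the accounting
#' reproduces those totals; see [network_registry()].
NULL

network_layer_plan <- function(arch, input_shape, n_classes, opts = list()) {
  o <- function(name, default) opts[[name]] %||% default
  switch(arch,
    lnn = list(layer_flatten(), layer_dense(n_classes, bias = FALSE)),
    scnn = list(
      layer_conv_time(o("n_filters", 40), o("kernel_time", 25), bias = TRUE),
      layer_conv_spat(o("n_filters", 40), bias = FALSE),
      layer_batchnorm(),
      layer_square(),
      layer_meanpool(o("pool", 360)),
      layer_log(),
      layer_dropout(0.5),
      layer_flatten(),
      layer_dense(n_classes, bias = TRUE)
    ),
    dcnn = {
      fs <- o("n_filters", c(25, 50, 100, 200))
      ks <- o("kernels", c(16, 10, 10, 10))
      ps <- o("pools", c(3, 9, 9, 10))
      c(list(
          layer_conv_time(fs[1], ks[1], bias = FALSE),
          layer_conv_spat(fs[1], bias = FALSE),
          layer_batchnorm(), layer_elu(),
          layer_meanpool(ps[1]), layer_dropout(0.5)),
        unlist(lapply(2:4, function(i) list(
          layer_conv_map(fs[i], ks[i], bias = FALSE),
          layer_batchnorm(), layer_elu(),
          layer_meanpool(ps[i]), layer_dropout(0.5))), recursive = FALSE),
        list(layer_flatten(), layer_dense(n_classes, bias = TRUE)))
    },
    eegnet = list(
      layer_conv_time(o("F1", 8), o("kernel_time", 50), bias = FALSE,
                      pad_same = TRUE),
      layer_batchnorm(),
      layer_depthwise_spat(o("D", 2), bias = FALSE),
      layer_batchnorm(), layer_elu(),
      layer_meanpool(o("pool1", 8)), layer_dropout(0.25),
      layer_sep_depthwise(o("kernel_sep", 16), bias = FALSE),
      layer_pointwise(o("F1", 8) * o("D", 2), bias = FALSE),
      layer_batchnorm(), layer_elu(),
      layer_meanpool(o("pool2", 10)), layer_dropout(0.25),
      layer_flatten(),
      layer_dense(n_classes, bias = FALSE)
    ),
    stop("unknown architecture: ", arch)
  )
}

#' Build a network with initialized weights
#'
#' @param arch `"lnn"`, `"scnn"`, `"dcnn"` or `"eegnet"`.
#' @param input_shape `c(channels, samples)`; the canonical input is
#'   `c(19, 30000)`. Smaller shapes (with adapted `opts`) support
#'   scaled-down experiments.
#' @param n_classes Number of classes (2).
#' @param seed Seed for weight initialization.
#' @param opts Named list of architecture overrides (kernel/pool/filter
#'   sizes) for non-canonical input shapes.
#' @return An `eeg_network` object.
#' @export
build_network <- function(arch = c("lnn", "scnn", "dcnn", "eegnet"),
                          input_shape = c(19, 30000), n_classes = 2,
                          seed = 1, opts = list()) {
  arch <- match.arg(arch)
  set.seed(seed)
  plan <- network_layer_plan(arch, input_shape, n_classes, opts)
  s <- c(1, input_shape[1], input_shape[2])
  layers <- vector("list", length(plan))
  for (i in seq_along(plan)) {
    layers[[i]] <- nn_init_layer(plan[[i]], s)
    s <- layers[[i]]$out_shape
    if (any(s < 1))
      stop("layer ", i, " (", plan[[i]]$type,
           ") collapses the input; shape too small for this plan")
  }
  structure(
    list(arch = arch, input_shape = input_shape, n_classes = n_classes,
         layers = layers, seed = seed, opts = opts),
    class = "eeg_network"
  )
}

#' Count trainable weights
#'
#' Sum of the sizes of every allocated parameter array (convolution and
#' dense weights, biases where present, batch-norm affine pairs).
#'
#' @param net An `eeg_network`.
#' @return Integer total.
#' @export
count_weights <- function(net) {
  sum(vapply(net$layers, function(l)
    sum(vapply(l$params, length, 0L)), 0L))
}

#' Per-layer architecture registry
#'
#' @param net An `eeg_network`.
#' @return Data frame: layer type, output shape, parameter count.
#' @export
network_registry <- function(net) {
  data.frame(
    layer = vapply(net$layers, `[[`, "", "type"),
    out_shape = vapply(net$layers, function(l)
      paste(l$out_shape, collapse = "x"), ""),
    n_params = vapply(net$layers, function(l)
      sum(vapply(l$params, length, 0L)), 0L)
  )
}

#' @export
print.eeg_network <- function(x, ...) {
  cat(sprintf("<eeg_network %s: input %s, %d classes, %s weights>\n",
              toupper(x$arch), paste(x$input_shape, collapse = "x"),
              x$n_classes, format(count_weights(x), big.mark = ",")))
  invisible(x)
}

# segments (list of canonical_segment or channels x time matrices) -> 4D
segments_to_tensor <- function(segments) {
  mats <- lapply(segments, function(s) if (is.matrix(s)) s else s$data)
  d <- dim(mats[[1]])
  x <- array(0, dim = c(1, d[1], d[2], length(mats)))
  for (b in seq_along(mats)) x[1, , , b] <- mats[[b]]
  x
}

net_accuracy_loss <- function(net, x, y_int) {
  fw <- nn_forward(net, x, training = FALSE)
  probs <- nn_softmax(fw$out)
  pred <- apply(probs, 2, which.max)
  loss <- -mean(log(pmax(probs[cbind(y_int, seq_len(ncol(probs)))], 1e-12)))
  list(accuracy = mean(pred == y_int), loss = loss, probs = probs)
}

train_epochs <- function(net, x, y_int, epochs, batch_size, lr, seed,
                         stop_loss = NULL) {
  state <- adam_init(net)
  n <- dim(x)[4]; t_step <- 0
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     train_accuracy = numeric(0))
  for (ep in seq_len(epochs)) {
    set.seed(mix_seed(seed, ep))
    ord <- sample(n)
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    for (bt in batches) {
      xb <- x[, , , bt, drop = FALSE]
      lg <- nn_loss_grads(net, xb, y_int[bt], training = TRUE)
      net <- lg$net                       # running BN stats
      t_step <- t_step + 1
      up <- adam_step(net, lg$grads, state, t_step, lr = lr)
      net <- up$net; state <- up$state
    }
    ev <- net_accuracy_loss(net, x, y_int)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ev$loss,
                                   train_accuracy = ev$accuracy))
    if (!is.null(stop_loss) && ev$loss <= stop_loss) break
  }
  list(net = net, history = hist)
}

#' Two-run training protocol
#'
#' Run 1 trains for a fixed number of epochs (35 by default), recording
#' per-epoch training accuracy and loss; the best epoch is the one with
#' the highest training accuracy (ties to the earliest). Run 2 restarts
#' from freshly initialized weights and stops at the first epoch whose
#' training loss reaches run 1's loss at the best epoch, capped at the
#' same epoch budget (with a warning if the cap is hit). A 10% validation
#' split is carved from the training partition for monitoring only; it
#' never overlaps test data. Optimization is Adam on the softmax
#' cross-entropy.
#'
#' @param net An `eeg_network` (untrained; defines arch and shapes).
#' @param segments Training segments (list of `canonical_segment`s or
#'   channels x time matrices).
#' @param labels Training labels (two classes).
#' @param config List: `run1_epochs` (35), `batch_size` (64), `lr`
#'   (1e-3), `val_fraction` (0.1), `seed` (1), `restart` (`"fresh"` or
#'   `"warm"`).
#' @return List: `net` (trained, from run 2), `run1`, `run2` (histories),
#'   `best_epoch`, `target_loss`, `validation` (per-run-1-epoch accuracy),
#'   `classes`.
#' @export
train_two_run <- function(net, segments, labels, config = list()) {
  cfg <- modifyList(list(run1_epochs = 35, batch_size = 64, lr = 1e-3,
                         val_fraction = 0.1, seed = 1, restart = "fresh"),
                    config)
  classes <- sort(unique(as.character(labels)))
  y_int <- match(as.character(labels), classes)
  x <- segments_to_tensor(segments)
  if (!all(dim(x)[2:3] == net$input_shape))
    stop("segment shape does not match the network input shape",
         call. = FALSE)

  # validation carve-out (monitoring only)
  set.seed(mix_seed(cfg$seed, 999))
  n <- dim(x)[4]
  n_val <- max(1L, floor(cfg$val_fraction * n))
  val_idx <- sample(n, n_val)
  tr_idx <- setdiff(seq_len(n), val_idx)
  xt <- x[, , , tr_idx, drop = FALSE]; yt <- y_int[tr_idx]
  xv <- x[, , , val_idx, drop = FALSE]; yv <- y_int[val_idx]

  run1 <- train_epochs(net, xt, yt, cfg$run1_epochs, cfg$batch_size,
                       cfg$lr, mix_seed(cfg$seed, 1))
  best_epoch <- which.max(run1$history$train_accuracy)  # ties -> earliest
  target_loss <- run1$history$train_loss[best_epoch]
  val_acc <- net_accuracy_loss(run1$net, xv, yv)$accuracy

  net2 <- if (identical(cfg$restart, "warm")) run1$net
          else build_network(net$arch, net$input_shape, net$n_classes,
                             seed = mix_seed(net$seed, 2), opts = net$opts)
  run2 <- train_epochs(net2, xt, yt, cfg$run1_epochs, cfg$batch_size,
                       cfg$lr, mix_seed(cfg$seed, 2),
                       stop_loss = target_loss)
  if (utils::tail(run2$history$train_loss, 1) > target_loss)
    warning("run 2 hit the epoch cap before reaching the target loss")

  list(net = run2$net, run1 = run1$history, run2 = run2$history,
       best_epoch = best_epoch, target_loss = target_loss,
       validation = val_acc, classes = classes, config = cfg)
}

#' Test accuracy of a trained network
#'
#' Per segment, the predicted class is the argmax of the softmax output;
#' the result is the fraction correct.
#'
#' @param model A [train_two_run()] result (or a bare `eeg_network` plus
#'   `classes`).
#' @param segments Test segments.
#' @param labels True test labels.
#' @return Accuracy in [0, 1].
#' @export
network_predict_accuracy <- function(model, segments, labels) {
  if (length(segments) == 0) stop("empty test set", call. = FALSE)
  net <- if (inherits(model, "eeg_network")) model else model$net
  classes <- if (inherits(model, "eeg_network"))
    sort(unique(as.character(labels))) else model$classes
  x <- segments_to_tensor(segments)
  ev <- net_accuracy_loss(net, x, match(as.character(labels), classes))
  ev$accuracy
}

#' Class probabilities of a trained network
#'
#' @param model A [train_two_run()] result or `eeg_network`.
#' @param segments Segments to score.
#' @return Matrix (classes x segments) of softmax probabilities.
#' @export
network_predict_proba <- function(model, segments) {
  net <- if (inherits(model, "eeg_network")) model else model$net
  x <- segments_to_tensor(segments)
  nn_softmax(nn_forward(net, x, training = FALSE)$out)
}
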