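# Minimal neural-network engine: forward and backward passes for the layer
# vocabulary the four EEG architectures need, plus Adam. Tensors are 4D
# arrays dim (maps, channels, time, batch); after the spatial convolution
# the channel axis collapses to 1; `flatten` switches to a (features x
# batch) matrix consumed by `dense`.
#
# Every layer is a list: type, hyper-parameters, `params` (named arrays).
# nn_forward() returns per-layer caches; nn_backward() returns per-layer
# gradients in the same shapes as `params`.

nn_init_mat <- function(nr, nc, fan_in, rng_sd = NULL) {
  sd <- rng_sd %||% sqrt(2 / max(fan_in, 1))
  matrix(rnorm(nr * nc, sd = sd), nr, nc)
}

layer_conv_time <- function(n_filters, kernel, bias = TRUE, pad_same = FALSE) {
  list(type = "conv_time", n_filters = n_filters, kernel = kernel,
       bias = bias, pad_same = pad_same, params = NULL)
}
layer_conv_spat <- function(n_filters, bias = FALSE)
  list(type = "conv_spat", n_filters = n_filters, bias = bias, params = NULL)
layer_depthwise_spat <- function(depth_mult, bias = FALSE)
  list(type = "depthwise_spat", depth_mult = depth_mult, bias = bias,
       params = NULL)
layer_conv_map <- function(n_filters, kernel, bias = FALSE)
  list(type = "conv_map", n_filters = n_filters, kernel = kernel,
       bias = bias, params = NULL)
layer_sep_depthwise <- function(kernel, bias = FALSE)
  list(type = "sep_depthwise", kernel = kernel, bias = bias, params = NULL)
layer_pointwise <- function(n_filters, bias = FALSE)
  list(type = "pointwise", n_filters = n_filters, bias = bias, params = NULL)
layer_batchnorm <- function() list(type = "batchnorm", params = NULL,
                                   eps = 1e-5, momentum = 0.1)
layer_elu <- function() list(type = "elu", params = NULL)
layer_square <- function() list(type = "square", params = NULL)
layer_log <- function(eps = 1e-7) list(type = "log", eps = eps, params = NULL)
layer_meanpool <- function(pool) list(type = "meanpool", pool = pool,
                                      params = NULL)
layer_dropout <- function(p) list(type = "dropout", p = p, params = NULL)
layer_flatten <- function() list(type = "flatten", params = NULL)
layer_dense <- function(n_out, bias = TRUE)
  list(type = "dense", n_out = n_out, bias = bias, params = NULL)

# shape: c(maps, channels, time) or c(features) after flatten
nn_out_shape <- function(layer, s) {
  switch(layer$type,
    conv_time = c(layer$n_filters, s[2],
                  if (layer$pad_same) s[3] else s[3] - layer$kernel + 1),
    conv_spat = c(layer$n_filters, 1, s[3]),
    depthwise_spat = c(s[1] * layer$depth_mult, 1, s[3]),
    conv_map = c(layer$n_filters, 1, s[3] - layer$kernel + 1),
    sep_depthwise = s,
    pointwise = c(layer$n_filters, s[2], s[3]),
    meanpool = c(s[1], s[2], s[3] %/% layer$pool),
    flatten = prod(s),
    dense = layer$n_out,
    s
  )
}

# allocate parameters given the input shape; returns the completed layer
nn_init_layer <- function(layer, s) {
  p <- list()
  switch(layer$type,
    conv_time = {
      p$W <- nn_init_mat(layer$n_filters, layer$kernel, layer$kernel)
      if (layer$bias) p$b <- numeric(layer$n_filters)
    },
    conv_spat = {
      d <- s[1] * s[2]
      p$W <- nn_init_mat(layer$n_filters, d, d)
      if (layer$bias) p$b <- numeric(layer$n_filters)
    },
    depthwise_spat = {
      # W[d, c, f]: depth filters per input map
      p$W <- array(rnorm(layer$depth_mult * s[2] * s[1],
                         sd = sqrt(2 / s[2])),
                   dim = c(layer$depth_mult, s[2], s[1]))
      if (layer$bias) p$b <- numeric(layer$depth_mult * s[1])
    },
    conv_map = {
      d <- s[1] * layer$kernel
      p$W <- nn_init_mat(layer$n_filters, d, d)
      if (layer$bias) p$b <- numeric(layer$n_filters)
    },
    sep_depthwise = {
      p$W <- nn_init_mat(s[1], layer$kernel, layer$kernel)
      if (layer$bias) p$b <- numeric(s[1])
    },
    pointwise = {
      p$W <- nn_init_mat(layer$n_filters, s[1], s[1])
      if (layer$bias) p$b <- numeric(layer$n_filters)
    },
    batchnorm = {
      p$gamma <- rep(1, s[1]); p$beta <- numeric(s[1])
      layer$run_mean <- numeric(s[1]); layer$run_var <- rep(1, s[1])
    },
    dense = {
      p$W <- nn_init_mat(layer$n_out, s[1], s[1])
      if (layer$bias) p$b <- numeric(layer$n_out)
    }
  )
  layer$params <- p
  layer$in_shape <- s
  layer$out_shape <- nn_out_shape(layer, s)
  layer
}

pad_time <- function(x, k) {
  # symmetric "same" padding for kernel k: left ceil((k-1)/2), right floor
  d <- dim(x)
  left <- ceiling((k - 1) / 2); right <- (k - 1) - left
  out <- array(0, dim = c(d[1], d[2], d[3] + k - 1, d[4]))
  out[, , (left + 1):(left + d[3]), ] <- x
  out
}

nn_layer_forward <- function(layer, x, training = FALSE) {
  p <- layer$params
  cache <- list(x = x)
  out <- switch(layer$type,
    conv_time = {
      xin <- if (layer$pad_same) pad_time(x, layer$kernel) else x
      d <- dim(xin); k <- layer$kernel; T2 <- d[3] - k + 1
      B <- d[4]; C <- d[2]
      idx <- outer(seq_len(k), seq_len(T2) - 1L, `+`)
      y <- array(0, dim = c(layer$n_filters, C, T2, B))
      for (b in seq_len(B)) for (c in seq_len(C)) {
        Z <- matrix(xin[1, c, , b][idx], k, T2)
        y[, c, , b] <- p$W %*% Z
      }
      if (layer$bias) y <- y + array(p$b, dim = dim(y))
      cache$xpad <- xin; cache$idx <- idx
      y
    },
    conv_spat = {
      d <- dim(x); B <- d[4]
      y <- array(0, dim = c(layer$n_filters, 1, d[3], B))
      for (b in seq_len(B)) {
        Xm <- matrix(x[, , , b], d[1] * d[2], d[3])
        y[, 1, , b] <- p$W %*% Xm
      }
      if (layer$bias) y <- y + array(p$b, dim = dim(y))
      y
    },
    depthwise_spat = {
      d <- dim(x); B <- d[4]; F1 <- d[1]; D <- layer$depth_mult
      y <- array(0, dim = c(F1 * D, 1, d[3], B))
      for (b in seq_len(B)) for (f in seq_len(F1)) {
        y[((f - 1) * D + 1):(f * D), 1, , b] <-
          matrix(p$W[, , f], D, d[2]) %*% x[f, , , b, drop = TRUE]
      }
      y
    },
    conv_map = {
      d <- dim(x); k <- layer$kernel; T2 <- d[3] - k + 1
      B <- d[4]; Fi <- d[1]
      y <- array(0, dim = c(layer$n_filters, 1, T2, B))
      for (b in seq_len(B)) {
        X <- matrix(x[, 1, , b], Fi, d[3])
        Z <- matrix(0, Fi * k, T2)
        for (j in seq_len(k))
          Z[((j - 1) * Fi + 1):(j * Fi), ] <- X[, j:(j + T2 - 1)]
        y[, 1, , b] <- p$W %*% Z
      }
      if (layer$bias) y <- y + array(p$b, dim = dim(y))
      y
    },
    sep_depthwise = {
      xin <- pad_time(x, layer$kernel)
      d <- dim(x); k <- layer$kernel
      y <- array(0, dim = d)
      for (j in seq_len(k))
        y <- y + p$W[, j] *
          xin[, , j:(j + d[3] - 1), , drop = FALSE]
      cache$xpad <- xin
      y
    },
    pointwise = {
      d <- dim(x); B <- d[4]
      y <- array(0, dim = c(layer$n_filters, 1, d[3], B))
      for (b in seq_len(B))
        y[, 1, , b] <- p$W %*% matrix(x[, 1, , b], d[1], d[3])
      if (layer$bias) y <- y + array(p$b, dim = dim(y))
      y
    },
    batchnorm = {
      # eval mode only; training mode goes through bn_forward_train()
      mu <- layer$run_mean; vr <- layer$run_var
      sdv <- sqrt(vr + layer$eps)
      xhat <- (x - mu) / sdv          # recycles along first dim
      cache$mu <- mu; cache$sdv <- sdv; cache$xhat <- xhat
      cache$training <- training
      p$gamma * xhat + p$beta
    },
    elu = ifelse(x > 0, x, exp(pmin(x, 0)) - 1),
    square = x * x,
    log = log(pmax(x, layer$eps)),
    meanpool = {
      d <- dim(x); pl <- layer$pool; T2 <- d[3] %/% pl
      y <- array(0, dim = c(d[1], d[2], T2, d[4]))
      for (t in seq_len(T2))
        y[, , t, ] <- apply(
          x[, , ((t - 1) * pl + 1):(t * pl), , drop = FALSE], c(1, 2, 4),
          mean)
      y
    },
    dropout = {
      if (training && layer$p > 0) {
        mask <- array(stats::rbinom(length(x), 1, 1 - layer$p) /
                        (1 - layer$p), dim = dim(x))
        cache$mask <- mask
        x * mask
      } else x
    },
    flatten = {
      d <- dim(x)
      matrix(x, prod(d[-length(d)]), d[length(d)])
    },
    dense = {
      y <- p$W %*% x
      if (layer$bias) y <- y + p$b
      y
    },
    stop("unknown layer type: ", layer$type)
  )
  list(out = out, cache = cache)
}

# batchnorm training-mode forward needs batch stats recorded; handled here
# (separate from nn_layer_forward's eval path for clarity)
bn_forward_train <- function(layer, x) {
  p <- layer$params
  mu <- apply(x, 1, mean)
  vr <- apply(x, 1, function(v) mean((v - mean(v))^2))
  sdv <- sqrt(vr + layer$eps)
  xhat <- (x - mu) / sdv
  list(out = p$gamma * xhat + p$beta,
       cache = list(x = x, mu = mu, sdv = sdv, xhat = xhat,
                    training = TRUE),
       mu = mu, vr = vr)
}

nn_layer_backward <- function(layer, cache, gy) {
  p <- layer$params
  grads <- list()
  gx <- switch(layer$type,
    conv_time = {
      xin <- cache$xpad; idx <- cache$idx
      d <- dim(xin); k <- layer$kernel
      T2 <- dim(gy)[3]; B <- d[4]; C <- d[2]
      dW <- matrix(0, layer$n_filters, k)
      dxp <- array(0, dim = d)
      for (b in seq_len(B)) for (c in seq_len(C)) {
        G <- matrix(gy[, c, , b], layer$n_filters, T2)
        Z <- matrix(xin[1, c, , b][idx], k, T2)
        dW <- dW + G %*% t(Z)
        dZ <- crossprod(p$W, G)
        xg <- numeric(d[3])
        for (j in seq_len(k))
          xg[j:(j + T2 - 1)] <- xg[j:(j + T2 - 1)] + dZ[j, ]
        dxp[1, c, , b] <- xg
      }
      grads$W <- dW
      if (layer$bias) grads$b <- apply(gy, 1, sum)
      if (layer$pad_same) {
        left <- ceiling((k - 1) / 2)
        Tin <- d[3] - k + 1
        dxp[, , (left + 1):(left + Tin), , drop = FALSE]
      } else dxp
    },
    conv_spat = {
      x <- cache$x; d <- dim(x); B <- d[4]
      dW <- matrix(0, nrow(p$W), ncol(p$W))
      gx <- array(0, dim = d)
      for (b in seq_len(B)) {
        Xm <- matrix(x[, , , b], d[1] * d[2], d[3])
        G <- matrix(gy[, 1, , b], layer$n_filters, d[3])
        dW <- dW + G %*% t(Xm)
        gx[, , , b] <- array(crossprod(p$W, G), dim = d[1:3])
      }
      grads$W <- dW
      if (layer$bias) grads$b <- apply(gy, 1, sum)
      gx
    },
    depthwise_spat = {
      x <- cache$x; d <- dim(x); B <- d[4]
      F1 <- d[1]; D <- layer$depth_mult
      dW <- array(0, dim = dim(p$W))
      gx <- array(0, dim = d)
      for (b in seq_len(B)) for (f in seq_len(F1)) {
        G <- matrix(gy[((f - 1) * D + 1):(f * D), 1, , b], D, d[3])
        X <- matrix(x[f, , , b], d[2], d[3])
        dW[, , f] <- dW[, , f] + G %*% t(X)
        gx[f, , , b] <- crossprod(matrix(p$W[, , f], D, d[2]), G)
      }
      grads$W <- dW
      gx
    },
    conv_map = {
      x <- cache$x; d <- dim(x); k <- layer$kernel
      T2 <- dim(gy)[3]; B <- d[4]; Fi <- d[1]
      dW <- matrix(0, nrow(p$W), ncol(p$W))
      gx <- array(0, dim = d)
      for (b in seq_len(B)) {
        X <- matrix(x[, 1, , b], Fi, d[3])
        Z <- matrix(0, Fi * k, T2)
        for (j in seq_len(k))
          Z[((j - 1) * Fi + 1):(j * Fi), ] <- X[, j:(j + T2 - 1)]
        G <- matrix(gy[, 1, , b], layer$n_filters, T2)
        dW <- dW + G %*% t(Z)
        dZ <- crossprod(p$W, G)
        dX <- matrix(0, Fi, d[3])
        for (j in seq_len(k))
          dX[, j:(j + T2 - 1)] <- dX[, j:(j + T2 - 1)] +
            dZ[((j - 1) * Fi + 1):(j * Fi), ]
        gx[, 1, , b] <- dX
      }
      grads$W <- dW
      if (layer$bias) grads$b <- apply(gy, 1, sum)
      gx
    },
    sep_depthwise = {
      xin <- cache$xpad; d <- dim(cache$x); k <- layer$kernel
      dW <- matrix(0, d[1], k)
      dxp <- array(0, dim = dim(xin))
      for (j in seq_len(k)) {
        seg <- xin[, , j:(j + d[3] - 1), , drop = FALSE]
        dW[, j] <- apply(gy * seg, 1, sum)
        dxp[, , j:(j + d[3] - 1), ] <-
          dxp[, , j:(j + d[3] - 1), , drop = FALSE] + p$W[, j] * gy
      }
      grads$W <- dW
      left <- ceiling((k - 1) / 2)
      dxp[, , (left + 1):(left + d[3]), , drop = FALSE]
    },
    pointwise = {
      x <- cache$x; d <- dim(x); B <- d[4]
      dW <- matrix(0, nrow(p$W), ncol(p$W))
      gx <- array(0, dim = d)
      for (b in seq_len(B)) {
        X <- matrix(x[, 1, , b], d[1], d[3])
        G <- matrix(gy[, 1, , b], layer$n_filters, d[3])
        dW <- dW + G %*% t(X)
        gx[, 1, , b] <- crossprod(p$W, G)
      }
      grads$W <- dW
      if (layer$bias) grads$b <- apply(gy, 1, sum)
      gx
    },
    batchnorm = {
      xhat <- cache$xhat; sdv <- cache$sdv
      d <- dim(xhat); m <- prod(d[-1])
      grads$gamma <- apply(gy * xhat, 1, sum)
      grads$beta <- apply(gy, 1, sum)
      if (isTRUE(cache$training)) {
        gxh <- gy * p$gamma
        s1 <- apply(gxh, 1, sum)
        s2 <- apply(gxh * xhat, 1, sum)
        (gxh - s1 / m - xhat * (s2 / m)) / sdv
      } else {
        gy * p$gamma / sdv
      }
    },
    elu = gy * ifelse(cache$x > 0, 1, exp(pmin(cache$x, 0))),
    square = gy * 2 * cache$x,
    log = gy * (cache$x > layer$eps) / pmax(cache$x, layer$eps),
    meanpool = {
      d <- dim(cache$x); pl <- layer$pool; T2 <- dim(gy)[3]
      gx <- array(0, dim = d)
      for (t in seq_len(T2))
        gx[, , ((t - 1) * pl + 1):(t * pl), ] <-
          gy[, , rep(t, pl), , drop = FALSE] / pl
      gx
    },
    dropout = if (!is.null(cache$mask)) gy * cache$mask else gy,
    flatten = array(gy, dim = dim(cache$x)),
    dense = {
      grads$W <- gy %*% t(cache$x)
      if (layer$bias) grads$b <- rowSums(gy)
      crossprod(p$W, gy)
    }
  )
  list(gx = gx, grads = grads)
}

# forward through all layers; returns output and caches
nn_forward <- function(net, x, training = FALSE) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    layer <- net$layers[[i]]
    if (layer$type == "batchnorm" && training) {
      fw <- bn_forward_train(layer, x)
      # update running stats
      mom <- layer$momentum
      net$layers[[i]]$run_mean <- (1 - mom) * layer$run_mean + mom * fw$mu
      net$layers[[i]]$run_var <- (1 - mom) * layer$run_var + mom * fw$vr
    } else {
      fw <- nn_layer_forward(layer, x, training = training)
    }
    caches[[i]] <- fw$cache
    x <- fw$out
  }
  list(out = x, caches = caches, net = net)
}

nn_softmax <- function(scores) {
  z <- sweep(scores, 2, apply(scores, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# cross-entropy loss + full backward; y: integer class ids (1-based) per
# batch column. Returns loss, per-layer grads, probs.
nn_loss_grads <- function(net, x, y, training = TRUE) {
  fw <- nn_forward(net, x, training = training)
  net <- fw$net
  probs <- nn_softmax(fw$out)
  B <- ncol(probs)
  loss <- -mean(log(pmax(probs[cbind(y, seq_len(B))], 1e-12)))
  g <- probs
  g[cbind(y, seq_len(B))] <- g[cbind(y, seq_len(B))] - 1
  g <- g / B
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    bw <- nn_layer_backward(net$layers[[i]], fw$caches[[i]], g)
    grads[[i]] <- bw$grads
    g <- bw$gx
  }
  list(loss = loss, grads = grads, probs = probs, net = net)
}

adam_init <- function(net) {
  lapply(net$layers, function(l)
    lapply(l$params, function(p) list(m = p * 0, v = p * 0)))
}

adam_step <- function(net, grads, state, t, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(net$layers)) {
    for (nm in names(net$layers[[i]]$params)) {
      g <- grads[[i]][[nm]]
      if (is.null(g)) next
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      net$layers[[i]]$params[[nm]] <-
        net$layers[[i]]$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[nm]] <- st
    }
  }
  list(net = net, state = state)
}
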