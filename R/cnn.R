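# Small spectrogram CNN: 4 blocks of (3x3 conv -> ReLU -> 2x2 max pool) with
# channel widths 8-16-32-32, then a softmax head. Stands in for the
# full-scale image classifiers at desk scale; batch size 32 is retained and
# the step budget is config-exposed (default 2000, scaled down from the
# 200,000-iteration full-scale budget). Requires the image side to be a
# multiple of 16.

cnn_channels <- c(8L, 16L, 32L, 32L)

cnn_init <- function(image_size, n_classes) {
  if (image_size %% 16 != 0) stop("cnn image size must be a multiple of 16")
  cin <- 1L
  layers <- list()
  for (i in seq_along(cnn_channels)) {
    co <- cnn_channels[i]
    fan_in <- 9 * cin
    layers[[i]] <- list(W = matrix(rnorm(9 * cin * co, 0, sqrt(2 / fan_in)),
                                   9 * cin, co),
                        b = rep(0, co))
    cin <- co
  }
  flat <- (image_size / 16)^2 * cin
  list(layers = layers,
       head = list(W = matrix(rnorm(flat * n_classes, 0, sqrt(1 / flat)),
                              flat, n_classes),
                   b = rep(0, n_classes)),
       image_size = image_size)
}

cnn_forward <- function(net, img, keep = FALSE) {
  x <- array(img, c(nrow(img), ncol(img), 1L))
  cache <- list()
  for (i in seq_along(net$layers)) {
    z <- cs_conv_fw(x, net$layers[[i]]$W, net$layers[[i]]$b)
    a <- z * (z > 0)
    pl <- cs_pool_fw(a)
    if (keep) cache[[i]] <- list(x = x, z = z, idx = pl$idx,
                                 dim = dim(a))
    x <- pl$Y
  }
  flat <- as.numeric(x)
  logits <- as.numeric(crossprod(net$head$W, flat)) + net$head$b
  list(logits = logits, flat = flat, flat_dim = dim(x), cache = cache)
}

softmax <- function(z) { e <- exp(z - max(z)); e / sum(e) }

cnn_backward <- function(net, fwd, target) {
  p <- softmax(fwd$logits)
  dlogits <- p
  dlogits[target] <- dlogits[target] - 1
  grads <- list(head = list(W = outer(fwd$flat, dlogits), b = dlogits))
  dflat <- as.numeric(net$head$W %*% dlogits)
  dx <- array(dflat, fwd$flat_dim)
  for (i in rev(seq_along(net$layers))) {
    cc <- fwd$cache[[i]]
    da <- cs_pool_bw(dx, cc$idx, cc$dim[1], cc$dim[2])
    dz <- da * (cc$z > 0)
    bw <- cs_conv_bw(cc$x, net$layers[[i]]$W, dz)
    grads$layers[[i]] <- list(W = bw$dW, b = as.numeric(bw$db))
    dx <- bw$dX
  }
  list(grads = grads, loss = -log(max(p[target], 1e-12)))
}

cnn_train <- function(images, labels, config) {
  classes <- sort(unique(labels))
  y <- match(labels, classes)
  sz <- config$cnn_image_size
  if (!all(vapply(images, function(im) all(dim(im) == sz), logical(1))))
    stop("all images must be ", sz, "x", sz)
  with_seed(config$seed, {
    net <- cnn_init(sz, length(classes))
    n <- length(images)
    loss_hist <- numeric(config$cnn_max_steps)
    lr <- config$cnn_lr
    for (step in seq_len(config$cnn_max_steps)) {
      batch <- sample(n, min(config$cnn_batch_size, n), replace = n <
                        config$cnn_batch_size)
      gsum <- NULL
      lsum <- 0
      for (b in batch) {
        fwd <- cnn_forward(net, images[[b]], keep = TRUE)
        bw <- cnn_backward(net, fwd, y[b])
        lsum <- lsum + bw$loss
        gsum <- if (is.null(gsum)) bw$grads else acc_grads(gsum, bw$grads)
      }
      m <- length(batch)
      for (i in seq_along(net$layers)) {
        net$layers[[i]]$W <- net$layers[[i]]$W - lr * gsum$layers[[i]]$W / m
        net$layers[[i]]$b <- net$layers[[i]]$b - lr * gsum$layers[[i]]$b / m
      }
      net$head$W <- net$head$W - lr * gsum$head$W / m
      net$head$b <- net$head$b - lr * gsum$head$b / m
      loss_hist[step] <- lsum / m
    }
    list(net = net, classes = classes, loss_history = loss_hist)
  })
}

acc_grads <- function(a, b) {
  for (i in seq_along(a$layers)) {
    a$layers[[i]]$W <- a$layers[[i]]$W + b$layers[[i]]$W
    a$layers[[i]]$b <- a$layers[[i]]$b + b$layers[[i]]$b
  }
  a$head$W <- a$head$W + b$head$W
  a$head$b <- a$head$b + b$head$b
  a
}

cnn_predict <- function(state, images, classes) {
  scores <- t(vapply(images, function(im)
    softmax(cnn_forward(state$net, im)$logits),
    numeric(length(state$classes))))
  colnames(scores) <- state$classes
  list(labels = state$classes[max.col(scores, ties.method = "first")],
       scores = scores)
}
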