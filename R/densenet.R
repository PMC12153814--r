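# Minimal fully-connected network engine: ReLU hidden layers (optionally
# batch-normalized, optionally identity at chosen layers), linear or softmax
# output, inverted dropout, L1/L2 penalties, Adam updates, mini-batch
# training with optional validation monitoring and early stopping. Internal
# to the autoencoder and FFNN wrappers.

net_init <- function(widths, batch_norm = FALSE,
                     linear_hidden = integer(0)) {
  layers <- vector("list", length(widths) - 1)
  for (i in seq_along(layers)) {
    fan_in <- widths[i]
    layers[[i]] <- list(
      W = matrix(stats::rnorm(fan_in * widths[i + 1], 0,
                              sqrt(2 / fan_in)), fan_in, widths[i + 1]),
      b = rep(0, widths[i + 1])
    )
  }
  bn <- if (batch_norm)
    lapply(widths[-c(1, length(widths))], bn_init)
  else NULL
  structure(list(layers = layers, widths = widths, bn = bn,
                 linear_hidden = linear_hidden), class = "dense_net")
}

relu <- function(x) (x + abs(x)) / 2

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward pass. Returns per-layer activations (a[[1]] = input), dropout
# masks, batch-norm caches, and the net (running statistics are updated in
# training mode). Dropout and batch norm act on hidden layers only.
net_forward <- function(net, x, dropout = 0, training = FALSE,
                        output = c("linear", "softmax")) {
  output <- match.arg(output)
  L <- length(net$layers)
  a <- vector("list", L + 1)
  masks <- vector("list", L)
  bn_caches <- vector("list", L)
  a[[1]] <- x
  for (i in seq_len(L)) {
    z <- a[[i]] %*% net$layers[[i]]$W
    z <- sweep(z, 2, net$layers[[i]]$b, "+")
    if (i < L) {
      if (!is.null(net$bn)) {
        bf <- bn_forward(net$bn[[i]], z, training)
        net$bn[[i]] <- bf$bn
        bn_caches[[i]] <- bf
        z <- bf$y
      }
      h <- if (i %in% net$linear_hidden) z else relu(z)
      if (training && dropout > 0) {
        m <- matrix(stats::runif(length(h)) >= dropout, nrow(h), ncol(h))
        h <- h * m / (1 - dropout)
        masks[[i]] <- m
      }
      a[[i + 1]] <- h
    } else {
      a[[i + 1]] <- if (output == "softmax") softmax_rows(z) else z
    }
  }
  list(a = a, masks = masks, bn_caches = bn_caches, net = net)
}

# Mean loss over rows. For softmax y is a one-hot matrix.
net_loss <- function(pred, y, output) {
  if (output == "softmax") -mean(rowSums(y * log(pmax(pred, 1e-12))))
  else mean((pred - y)^2)
}

# Backward pass; returns per-layer gradients (W, b, and gamma/beta when the
# net is batch-normalized). For both losses the output delta has the same
# linear form (MSE with linear output; cross-entropy with softmax).
net_gradients <- function(net, fw, y, output, dropout) {
  L <- length(net$layers)
  n <- nrow(y)
  grads <- vector("list", L)
  delta <- if (output == "softmax") (fw$a[[L + 1]] - y) / n
           else 2 * (fw$a[[L + 1]] - y) / (n * ncol(y))
  for (i in L:1) {
    grads[[i]]$W <- crossprod(fw$a[[i]], delta)
    grads[[i]]$b <- colSums(delta)
    if (i > 1) {
      delta <- delta %*% t(net$layers[[i]]$W)
      if (dropout > 0 && !is.null(fw$masks[[i - 1]]))
        delta <- delta * fw$masks[[i - 1]] / (1 - dropout)
      if (!(i - 1) %in% net$linear_hidden) {
        # post-dropout activations are positive exactly where the ReLU was
        # active and the unit was kept; dropped units carry zero delta
        # already via the mask product above
        delta <- delta * (fw$a[[i]] > 0)
      }
      if (!is.null(net$bn)) {
        bb <- bn_backward(fw$bn_caches[[i - 1]], net$bn[[i - 1]], delta)
        grads[[i - 1]]$dgamma <- bb$dgamma
        grads[[i - 1]]$dbeta <- bb$dbeta
        delta <- bb$dz
      }
    }
  }
  grads
}

adam_state <- function(net) {
  lapply(seq_along(net$layers), function(i) {
    l <- net$layers[[i]]
    st <- list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
    if (!is.null(net$bn) && i < length(net$layers)) {
      st$mg <- st$vg <- net$bn[[i]]$gamma * 0
      st$mbe <- st$vbe <- net$bn[[i]]$beta * 0
    }
    st
  })
}

adam_step <- function(m, v, g, t, lr, beta1, beta2, eps = 1e-8) {
  m <- beta1 * m + (1 - beta1) * g
  v <- beta2 * v + (1 - beta2) * g^2
  upd <- lr * (m / (1 - beta1^t)) / (sqrt(v / (1 - beta2^t)) + eps)
  list(m = m, v = v, upd = upd)
}

adam_update <- function(net, grads, state, t, lr, beta1, beta2,
                        l2 = 0, l1 = 0) {
  for (i in seq_along(net$layers)) {
    gW <- grads[[i]]$W
    if (l2 > 0) gW <- gW + l2 * net$layers[[i]]$W
    if (l1 > 0) gW <- gW + l1 * sign(net$layers[[i]]$W)
    st <- state[[i]]
    s <- adam_step(st$mW, st$vW, gW, t, lr, beta1, beta2)
    st$mW <- s$m; st$vW <- s$v
    net$layers[[i]]$W <- net$layers[[i]]$W - s$upd
    s <- adam_step(st$mb, st$vb, grads[[i]]$b, t, lr, beta1, beta2)
    st$mb <- s$m; st$vb <- s$v
    net$layers[[i]]$b <- net$layers[[i]]$b - s$upd
    if (!is.null(net$bn) && !is.null(grads[[i]]$dgamma)) {
      s <- adam_step(st$mg, st$vg, grads[[i]]$dgamma, t, lr, beta1, beta2)
      st$mg <- s$m; st$vg <- s$v
      net$bn[[i]]$gamma <- net$bn[[i]]$gamma - s$upd
      s <- adam_step(st$mbe, st$vbe, grads[[i]]$dbeta, t, lr, beta1, beta2)
      st$mbe <- s$m; st$vbe <- s$v
      net$bn[[i]]$beta <- net$bn[[i]]$beta - s$upd
    }
    state[[i]] <- st
  }
  list(net = net, state = state)
}

# Train a dense net. x, y: matrices (y one-hot for softmax). val: optional
# list(x, y) monitored each epoch; with finite patience, training stops when
# the monitored loss has not improved for `patience` epochs and the best
# weights are restored.
net_train <- function(widths, x, y, output = c("linear", "softmax"),
                      epochs = 100, batch_size = 32, lr = 0.001,
                      beta1 = 0.9, beta2 = 0.999, l2 = 0, l1 = 0,
                      dropout = 0, val = NULL, patience = Inf, seed = 1L,
                      batch_norm = FALSE, linear_hidden = integer(0)) {
  output <- match.arg(output)
  if (any(!is.finite(x))) stop("non-finite values in training input")
  set.seed(as.integer(seed))
  net <- net_init(widths, batch_norm = batch_norm,
                  linear_hidden = linear_hidden)
  state <- adam_state(net)
  n <- nrow(x)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best <- list(loss = Inf, net = net, epoch = 0L)
  t <- 0
  eval_loss <- function(net, xe, ye) {
    pred <- net_forward(net, xe, output = output)$a[[length(widths)]]
    net_loss(pred, ye, output)
  }
  for (ep in seq_len(epochs)) {
    idx <- sample.int(n)
    for (start in seq(1, n, by = batch_size)) {
      rows <- idx[start:min(start + batch_size - 1, n)]
      xb <- x[rows, , drop = FALSE]
      yb <- y[rows, , drop = FALSE]
      fw <- net_forward(net, xb, dropout = dropout, training = TRUE,
                        output = output)
      net <- fw$net  # batch-norm running statistics
      if (!is.finite(net_loss(fw$a[[length(fw$a)]], yb, output)))
        stop("non-finite training loss; aborting")
      grads <- net_gradients(net, fw, yb, output, dropout)
      t <- t + 1
      up <- adam_update(net, grads, state, t, lr, beta1, beta2,
                        l2 = l2, l1 = l1)
      net <- up$net; state <- up$state
    }
    train_loss <- eval_loss(net, x, y)
    val_loss <- if (!is.null(val)) eval_loss(net, val$x, val$y) else NA_real_
    history <- rbind(history, data.frame(epoch = ep, train_loss = train_loss,
                                         val_loss = val_loss))
    monitored <- if (!is.null(val)) val_loss else train_loss
    if (monitored < best$loss - 1e-9) best <- list(loss = monitored, net = net,
                                                   epoch = ep)
    if (is.finite(patience) && ep - best$epoch >= patience) break
  }
  if (is.finite(patience)) net <- best$net
  list(net = net, history = history, output = output)
}

net_predict <- function(trained, x) {
  net_forward(trained$net, x, output = trained$output)$a[[length(trained$net$widths)]]
}
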