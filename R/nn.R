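# Minimal conv-net engine used by the autoencoder: conv2d / transposed
# conv2d ("same" padding) / max-pool layers with ReLU, MSE loss and Adam.
# Convolutions are im2col (C++) + one BLAS matmul; the transposed
# convolution is the exact adjoint of a strided convolution, so its forward
# pass is col2im and its backward pass is im2col with the same geometry.
# Arrays are dim (H, W, C, N).

# keras-style "same" padding: total = max((out-1)*stride + k - in, 0),
# more padding after than before.
pad_before_same <- function(in_side, out_side, k, stride) {
  max((out_side - 1L) * stride + k - in_side, 0L) %/% 2L
}

glorot_uniform <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

nn_layer_conv <- function(Cin, Cout, k, relu = TRUE) {
  list(type = "conv", k = as.integer(k), stride = 1L,
       Cin = Cin, Cout = Cout, relu = relu,
       W = glorot_uniform(k * k * Cin, Cout, k * k * Cin, k * k * Cout),
       b = numeric(Cout))
}

# weights stored in the layout of the associated downsampling conv:
# (k*k*Cout) x Cin
nn_layer_tconv <- function(Cin, Cout, k, stride, relu = TRUE) {
  list(type = "tconv", k = as.integer(k), stride = as.integer(stride),
       Cin = Cin, Cout = Cout, relu = relu,
       W = glorot_uniform(k * k * Cout, Cin, k * k * Cin, k * k * Cout),
       b = numeric(Cout))
}

nn_layer_pool <- function(p) list(type = "pool", p = as.integer(p))

nn_out_side <- function(layer, side) {
  switch(layer$type,
    conv = side,
    pool = side %/% layer$p,
    tconv = side * layer$stride)
}

# `slot` indexes the persistent C++ buffer pool; each layer owns one slot so
# the im2col buffer a forward pass leaves behind is the one its backward
# pass consumes.
nn_forward_layer <- function(layer, x, slot, training = FALSE) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  cache <- NULL
  if (layer$type == "conv") {
    pad <- pad_before_same(H, H, layer$k, 1L)
    y <- conv_layer_fwd(x, layer$W, layer$b, H, W, C, N, layer$k, pad,
                        TRUE, slot)
    if (training) cache <- list(y = y, in_dim = d, pad = pad)
  } else if (layer$type == "tconv") {
    Hb <- H * layer$stride
    pad <- pad_before_same(Hb, H, layer$k, layer$stride)
    y <- tconv_layer_fwd(x, layer$W, layer$b, H, W, C, N, layer$k,
                         layer$stride, pad, TRUE, slot)
    if (training) cache <- list(y = y, in_dim = d, pad = pad)
  } else {  # pool
    mp <- nn_maxpool(x, H, W, C, N, layer$p)
    y <- mp$y
    if (training) cache <- list(idx = mp$idx, in_dim = d)
  }
  list(y = y, cache = cache)
}

nn_backward_layer <- function(layer, dy, cache, slot) {
  d <- cache$in_dim; H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  if (layer$type == "conv") {
    conv_layer_bwd(layer$W, cache$y, dy, H, W, C, N,
                   layer$k, cache$pad, TRUE, slot)
  } else if (layer$type == "tconv") {
    tconv_layer_bwd(layer$W, cache$y, dy, H, W, C, N,
                    layer$k, layer$stride, cache$pad, TRUE, slot)
  } else {
    dx <- nn_maxpool_backward(dy, cache$idx, H, W, C, N)
    list(dx = dx, dW = NULL, db = NULL)
  }
}

nn_forward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    st <- nn_forward_layer(layers[[i]], x, i - 1L, training = training)
    x <- st$y
    caches[[i]] <- st$cache
  }
  list(y = x, caches = caches)
}

# returns per-layer gradients for loss = mean((y - target)^2)
nn_backward <- function(layers, caches, y, target) {
  dy <- 2 * (y - target) / length(y)
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    g <- nn_backward_layer(layers[[i]], dy, caches[[i]], i - 1L)
    dy <- g$dx
    grads[[i]] <- g[c("dW", "db")]
  }
  grads
}

adam_init <- function(layers) {
  lapply(layers, function(l) {
    if (is.null(l$W)) return(NULL)
    list(mW = 0 * l$W, vW = 0 * l$W, mb = 0 * l$b, vb = 0 * l$b)
  })
}

adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    if (is.null(grads[[i]]$dW)) next
    s <- state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * grads[[i]]$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * grads[[i]]$dW^2
    layers[[i]]$W <- layers[[i]]$W - lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps)
    s$mb <- beta1 * s$mb + (1 - beta1) * grads[[i]]$db
    s$vb <- beta2 * s$vb + (1 - beta2) * grads[[i]]$db^2
    layers[[i]]$b <- layers[[i]]$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[i]] <- s
  }
  list(layers = layers, state = state)
}
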