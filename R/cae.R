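#' Configuration of the convolutional autoencoder
#'
#' The default configuration is the full-scale architecture: 500 x 500
#' inputs, a 2 x 2 conv with 126 filters, a 5 x 5 conv with 256 filters,
#' two 2 x 2 max-pools down to a 125 x 125 x 256 bottleneck, and the
#' mirrored transposed convolutions back to a 500 x 500 x 1 ReLU output.
#' `scale` shrinks the input side and both filter counts together for
#' desk-scale runs; `input_side` and `filters` may also be set directly.
#'
#' @param input_side input image side in pixels (divisible by `pool^2`).
#' @param filters conv filter counts `(f1, f2)`.
#' @param kernels conv kernel sizes `(k1, k2)`.
#' @param pool max-pool size (and transposed-conv stride).
#' @param epochs training epochs (default 8).
#' @param batch_size minibatch size.
#' @param learning_rate Adam learning rate.
#' @param seed seed for weight initialization and batch shuffling.
#' @param scale multiplicative shrink factor applied to `input_side` and
#'   `filters`.
#' @return a `cae_config` list.
#' @export
cae_config <- function(input_side = 500L, filters = c(126L, 256L),
                       kernels = c(2L, 5L), pool = 2L, epochs = 8L,
                       batch_size = 8L, learning_rate = 1e-3, seed = 1L,
                       scale = 1) {
  check_number(scale, "scale", min = 1e-6)
  if (scale != 1) {
    input_side <- as.integer(round(input_side * scale))
    filters <- pmax(1L, as.integer(round(filters * scale)))
  }
  check_number(input_side, "input_side", min = 4, integerish = TRUE)
  check_number(pool, "pool", min = 1, integerish = TRUE)
  if (input_side %% pool^2 != 0L) {
    stop_validation(sprintf("`input_side` (%d) must be divisible by pool^2 (%d)",
                            input_side, pool^2))
  }
  if (length(filters) != 2L || any(filters < 1)) {
    stop_validation("`filters` must be two counts >= 1")
  }
  if (length(kernels) != 2L || any(kernels < 1)) {
    stop_validation("`kernels` must be two kernel sizes >= 1")
  }
  check_number(epochs, "epochs", min = 1, integerish = TRUE)
  check_number(batch_size, "batch_size", min = 1, integerish = TRUE)
  check_number(learning_rate, "learning_rate", min = 1e-12)
  check_number(seed, "seed", integerish = TRUE)
  structure(list(input_side = as.integer(input_side),
                 filters = as.integer(filters), kernels = as.integer(kernels),
                 pool = as.integer(pool), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "cae_config")
}

cae_layer_stack <- function(config) {
  f1 <- config$filters[1]; f2 <- config$filters[2]
  k1 <- config$kernels[1]; k2 <- config$kernels[2]
  p <- config$pool
  list(
    nn_layer_conv(1L, f1, k1),
    nn_layer_pool(p),
    nn_layer_conv(f1, f2, k2),
    nn_layer_pool(p),
    nn_layer_tconv(f2, f2, k2, p),
    nn_layer_tconv(f2, f1, k1, p),
    nn_layer_conv(f1, 1L, k1)
  )
}

#' Layer-by-layer output shapes of a configuration
#'
#' @param config a [cae_config()].
#' @return tibble with columns `layer`, `side`, `channels`; the row with
#'   the smallest side is the bottleneck.
#' @export
cae_shapes <- function(config) {
  layers <- cae_layer_stack(config)
  side <- config$input_side
  rows <- list(tibble(layer = "input", side = side, channels = 1L))
  nm <- c("conv1", "maxpool1", "conv2", "maxpool2", "tconv2", "tconv1", "conv_out")
  for (i in seq_along(layers)) {
    side <- nn_out_side(layers[[i]], side)
    ch <- if (layers[[i]]$type == "pool") rows[[i]]$channels else layers[[i]]$Cout
    rows[[i + 1]] <- tibble(layer = nm[i], side = side, channels = as.integer(ch))
  }
  dplyr::bind_rows(rows)
}

#' Build an untrained convolutional autoencoder
#'
#' Instantiates the layer stack with seeded Glorot-uniform weights. With
#' the default configuration the feature-map sides are
#' 500, 250, 250, 125, 250, 500, 500 and the bottleneck is 125 x 125 x 256.
#'
#' @param config a [cae_config()].
#' @return a `cae` object (untrained).
#' @export
build_cae <- function(config = cae_config()) {
  if (!inherits(config, "cae_config")) stop_validation("`config` must be a cae_config()")
  set.seed(config$seed)
  structure(list(config = config, layers = cae_layer_stack(config),
                 history = NULL, trained = FALSE),
            class = "cae")
}

#' @export
print.cae <- function(x, ...) {
  sh <- cae_shapes(x$config)
  cat(sprintf("<cae> input %dx%d, filters (%d, %d), bottleneck %dx%dx%d, %s\n",
              x$config$input_side, x$config$input_side,
              x$config$filters[1], x$config$filters[2],
              min(sh$side), min(sh$side), sh$channels[which.min(sh$side)],
              if (x$trained) sprintf("trained %d epochs", max(x$history$epoch))
              else "untrained"))
  invisible(x)
}

imgs_to_array <- function(imgs, side) {
  if (is.matrix(imgs)) imgs <- list(imgs)
  ok <- vapply(imgs, function(m) is.matrix(m) && all(dim(m) == side), logical(1))
  if (!all(ok)) {
    stop_validation(sprintf("all images must be %d x %d matrices", side, side))
  }
  array(unlist(imgs, use.names = FALSE), dim = c(side, side, 1L, length(imgs)))
}

cae_forward_batched <- function(model, imgs, batch = 8L) {
  side <- model$config$input_side
  if (is.matrix(imgs)) imgs <- list(imgs)
  n <- length(imgs)
  out <- vector("list", n)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch - 1L, n)
    x <- imgs_to_array(imgs[i:j], side)
    y <- nn_forward(model$layers, x)$y
    for (kk in i:j) out[[kk]] <- y[, , 1L, kk - i + 1L]
    i <- j + 1L
  }
  out
}

#' Train the autoencoder on artifact-free images
#'
#' Minimizes the mean squared error between input and reconstruction (the
#' input is its own target) with Adam. After each epoch the two validation
#' metrics are recorded on the clean/artifact validation sets: the mean
#' per-image MSE of artifact-free images and the percent difference between
#' the mean artifact-laden and artifact-free MSE. By default the weights of
#' the final epoch are kept; `select = "best_pct_diff"` instead restores
#' the epoch with the best clean/artifact differentiation, since minimal
#' clean MSE need not give the best separation.
#'
#' @param model an untrained (or previously trained) `cae`.
#' @param clean_train non-empty list of preprocessed clean images
#'   (`input_side` x `input_side` matrices in `[0, 1]`).
#' @param clean_val,artifact_val optional validation image lists; both are
#'   needed for the per-epoch metrics.
#' @param epochs,batch_size,learning_rate override the configuration.
#' @param select `"final"` or `"best_pct_diff"`.
#' @param verbose print one line per epoch.
#' @return the trained `cae` with a `history` tibble
#'   `(epoch, train_loss, mse_clean, pct_diff)`.
#' @export
train_cae <- function(model, clean_train, clean_val = NULL,
                      artifact_val = NULL, epochs = NULL, batch_size = NULL,
                      learning_rate = NULL, select = c("final", "best_pct_diff"),
                      verbose = FALSE) {
  if (!inherits(model, "cae")) stop_validation("`model` must be a cae")
  select <- match.arg(select)
  if (length(clean_train) == 0L) stop_validation("`clean_train` must be non-empty")
  cfg <- model$config
  epochs <- as.integer(epochs %||% cfg$epochs)
  batch_size <- as.integer(batch_size %||% cfg$batch_size)
  lr <- learning_rate %||% cfg$learning_rate
  side <- cfg$input_side
  X <- imgs_to_array(clean_train, side)
  n <- dim(X)[4]
  has_val <- !is.null(clean_val) && !is.null(artifact_val)
  if (select == "best_pct_diff" && !has_val) {
    stop_validation("`select = \"best_pct_diff\"` needs both validation sets")
  }
  layers <- model$layers
  state <- adam_init(layers)
  set.seed(derive_seed(cfg$seed, 1L))
  t_step <- 0L
  hist <- vector("list", epochs)
  best <- -Inf; best_layers <- NULL
  for (ep in seq_len(epochs)) {
    perm <- sample.int(n)
    losses <- c()
    i <- 1L
    while (i <= n) {
      j <- min(i + batch_size - 1L, n)
      xb <- X[, , , perm[i:j], drop = FALSE]
      fw <- nn_forward(layers, xb, training = TRUE)
      losses <- c(losses, mean((fw$y - xb)^2))
      grads <- nn_backward(layers, fw$caches, fw$y, xb)
      t_step <- t_step + 1L
      upd <- adam_step(layers, grads, state, lr, t_step)
      layers <- upd$layers; state <- upd$state
      i <- j + 1L
    }
    m <- model; m$layers <- layers
    vm <- if (has_val) validation_metrics(m, clean_val, artifact_val) else
      list(mse_clean = NA_real_, pct_diff = NA_real_)
    hist[[ep]] <- tibble(epoch = ep, train_loss = mean(losses),
                         mse_clean = vm$mse_clean, pct_diff = vm$pct_diff)
    if (has_val && is.finite(vm$pct_diff) && vm$pct_diff > best) {
      best <- vm$pct_diff
      if (select == "best_pct_diff") best_layers <- layers
    }
    if (verbose) {
      message(sprintf("epoch %d/%d: loss %.3g, mse_clean %.3g, pct_diff %.1f%%",
                      ep, epochs, mean(losses), vm$mse_clean, vm$pct_diff))
    }
  }
  model$layers <- if (select == "best_pct_diff") best_layers else layers
  model$history <- dplyr::bind_rows(hist)
  model$trained <- TRUE
  model$selection <- select
  model
}

#' Reconstruct one or more preprocessed images
#'
#' A single deterministic forward pass; the ReLU output layer guarantees
#' non-negative reconstructions of the same shape as the input.
#'
#' @param model a `cae`.
#' @param img an `input_side` x `input_side` matrix, or a list of them.
#' @return a matrix (or list of matrices) of reconstructions.
#' @export
reconstruct <- function(model, img) {
  if (!inherits(model, "cae")) stop_validation("`model` must be a cae")
  single <- is.matrix(img)
  out <- cae_forward_batched(model, img)
  if (single) out[[1]] else out
}

image_mse <- function(model, imgs) {
  rec <- cae_forward_batched(model, imgs)
  if (is.matrix(imgs)) imgs <- list(imgs)
  vapply(seq_along(imgs), function(i) mean((imgs[[i]] - rec[[i]])^2), numeric(1))
}

#' Validation metrics on clean and artifact-laden image sets
#'
#' @param model a `cae`.
#' @param clean_val,artifact_val non-empty lists of preprocessed images.
#' @return list with `mse_clean` (mean per-image MSE of the clean set) and
#'   `pct_diff` (percent difference of the artifact-laden mean MSE over the
#'   clean mean MSE).
#' @export
validation_metrics <- function(model, clean_val, artifact_val) {
  if (length(clean_val) == 0L || length(artifact_val) == 0L) {
    stop_validation("validation sets must be non-empty")
  }
  vm_from_mse(image_mse(model, clean_val), image_mse(model, artifact_val))
}

vm_from_mse <- function(clean_mses, artifact_mses) {
  mse_c <- mean(clean_mses)
  mse_a <- mean(artifact_mses)
  list(mse_clean = mse_c,
       pct_diff = if (mse_c == 0 && mse_a == 0) 0 else
         100 * (mse_a - mse_c) / mse_c)
}

#' Save / load a trained autoencoder
#'
#' One portable archive holding the configuration, weights and training
#' history; loading re-validates the layer stack against the configuration
#' arithmetic.
#'
#' @param model a `cae`.
#' @param path file path.
#' @return `read_cae` returns the `cae`.
#' @export
write_cae <- function(model, path) {
  if (!inherits(model, "cae")) stop_validation("`model` must be a cae")
  saveRDS(list(config = unclass(model$config),
               weights = lapply(model$layers, function(l) l[c("W", "b")]),
               history = model$history, trained = model$trained), path)
  invisible(path)
}

#' @rdname write_cae
#' @export
read_cae <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("model file '%s' not found", path))
  obj <- readRDS(path)
  cfg <- do.call(cae_config, obj$config[setdiff(names(obj$config), "scale")])
  model <- build_cae(cfg)
  for (i in seq_along(model$layers)) {
    w <- obj$weights[[i]]$W
    if (is.null(model$layers[[i]]$W) != is.null(w)) {
      stop_format("stored weights do not match the layer stack")
    }
    if (!is.null(w)) {
      if (!all(dim(w) == dim(model$layers[[i]]$W))) {
        stop_format(sprintf("layer %d weight shape mismatch", i))
      }
      model$layers[[i]]$W <- w
      model$layers[[i]]$b <- obj$weights[[i]]$b
    }
  }
  model$history <- obj$history
  model$trained <- obj$trained
  model
}
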