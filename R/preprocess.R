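#' Separable Gaussian blur with reflective borders
#'
#' A k x k Gaussian kernel (default 5 x 5) applied as two 1-D passes with
#' symmetric (reflective) padding, so constant images pass through unchanged
#' and the frame edge gains no dark rim that would survive thresholding.
#'
#' @param img numeric matrix.
#' @param kernel odd kernel size >= 3.
#' @param sigma Gaussian sigma in pixels; default is the size-derived
#'   `0.3 * ((kernel - 1) / 2 - 1) + 0.8` (1.1 for the 5 x 5 kernel), the
#'   convention widespread image libraries use when only a size is given.
#' @return float matrix of the same shape.
#' @export
gaussian_blur <- function(img, kernel = 5L, sigma = NULL) {
  check_matrix(img)
  check_number(kernel, "kernel", min = 3, integerish = TRUE)
  if (kernel %% 2L == 0L) stop_validation("`kernel` must be odd")
  sigma <- sigma %||% (0.3 * ((kernel - 1) / 2 - 1) + 0.8)
  check_number(sigma, "sigma", min = 1e-9)
  w <- gaussian_kernel_1d(kernel, sigma)
  img <- apply_separable(img, w)
  img
}

gaussian_kernel_1d <- function(kernel, sigma) {
  h <- (kernel - 1) / 2
  w <- exp(-((-h:h)^2) / (2 * sigma^2))
  w / sum(w)
}

# one separable pass per axis; symmetric padding (edge pixel mirrored,
# included): pad indices p..1 before and n..(n-p+1) after.
apply_separable <- function(x, w) {
  p <- (length(w) - 1L) / 2L
  conv1 <- function(m) {
    n <- nrow(m)
    padded <- m[c(p:1, 1:n, n:(n - p + 1L)), , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (i in seq_along(w)) {
      out <- out + w[i] * padded[i:(i + n - 1L), , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(x))))
}

#' Zero out background at mean + k standard deviations
#'
#' The screening threshold is computed on the blurred image over all pixels:
#' `t = mean + sd_mult * sd` (population SD). Pixels strictly below `t` are
#' set to zero; pixels at or above it are kept unchanged, so a constant
#' image (SD 0) passes through intact.
#'
#' @param img numeric matrix (typically the blurred image).
#' @param sd_mult SD multiplier, default 5.
#' @return matrix of the same shape.
#' @export
background_threshold <- function(img, sd_mult = 5) {
  check_matrix(img)
  check_number(sd_mult, "sd_mult", min = 0)
  m <- mean(img)
  s <- sqrt(mean((img - m)^2))  # population SD: fixed for reproducibility
  thr <- m + sd_mult * s
  img[img < thr] <- 0
  img
}

#' Non-overlapping block-mean downsampling
#'
#' Each `block x block` tile is replaced by its mean, halving (for the
#' default `block = 2`) the image side: 1000 x 1000 becomes 500 x 500.
#'
#' @param img numeric matrix with side divisible by `block`.
#' @param block block side in pixels.
#' @return matrix of side `nrow(img) / block`.
#' @export
block_reduce_mean <- function(img, block = 2L) {
  check_matrix(img)
  check_number(block, "block", min = 1, integerish = TRUE)
  n <- nrow(img); m <- ncol(img)
  if (n %% block != 0L || m %% block != 0L) {
    stop_validation(sprintf("image side (%d x %d) not divisible by block %d",
                            n, m, block))
  }
  g1 <- rep(seq_len(n %/% block), each = block)
  g2 <- rep(seq_len(m %/% block), each = block)
  out <- rowsum(img, g1)
  out <- t(rowsum(t(out), g2)) / block^2
  dimnames(out) <- NULL
  out
}

#' Normalize intensities to [0, 1] by the sensor full scale
#'
#' Divides by the fixed full-scale value `2^bit_depth - 1` (16383 for 14
#' bits) rather than the per-image maximum, so intensities stay comparable
#' across images and one model/threshold applies dataset-wide.
#'
#' @param img numeric matrix with values in `[0, 2^bit_depth - 1]`.
#' @param bit_depth sensor bit depth.
#' @return matrix with values in `[0, 1]`.
#' @export
normalize_image <- function(img, bit_depth = 14L) {
  check_matrix(img)
  check_number(bit_depth, "bit_depth", min = 1, integerish = TRUE)
  fs <- full_scale(bit_depth)
  if (any(img < 0)) stop_validation("negative intensities are not allowed")
  mx <- max(img)
  if (mx > fs) {
    stop_validation(sprintf("intensity %s exceeds full scale %s; upstream clipping violated",
                            format(mx), format(fs)))
  }
  img / fs
}

#' Preprocess a raw image into autoencoder input
#'
#' Composition of the four stages in order: Gaussian blur, background
#' zeroing at `mean + sd_mult * SD` of the blurred image, `block x block`
#' block-mean reduction, and full-scale normalization to `[0, 1]`. A
#' 1000 x 1000 raw frame becomes a 500 x 500 float image.
#'
#' @param raw integer-valued matrix (raw counts).
#' @param kernel,sigma blur parameters, see [gaussian_blur()].
#' @param sd_mult background threshold multiplier.
#' @param block block-reduction factor.
#' @param bit_depth sensor bit depth for normalization.
#' @return float matrix, side `nrow(raw) / block`, values in `[0, 1]`.
#' @export
preprocess_image <- function(raw, kernel = 5L, sigma = NULL, sd_mult = 5,
                             block = 2L, bit_depth = 14L) {
  check_matrix(raw, "raw")
  x <- gaussian_blur(raw, kernel = kernel, sigma = sigma)
  x <- background_threshold(x, sd_mult = sd_mult)
  x <- block_reduce_mean(x, block = block)
  normalize_image(x, bit_depth = bit_depth)
}

#' Preprocess a list of images or labeled images
#'
#' @param imgs list of matrices or `labeled_image`s.
#' @param ... passed to [preprocess_image()].
#' @return list of preprocessed float matrices (labels preserved in an
#'   attribute when the input was labeled).
#' @export
preprocess_images <- function(imgs, ...) {
  labels <- NULL
  if (length(imgs) && inherits(imgs[[1]], "labeled_image")) {
    labels <- vapply(imgs, function(x) x$label, character(1))
    imgs <- lapply(imgs, function(x) x$image)
  }
  out <- lapply(imgs, preprocess_image, ...)
  attr(out, "labels") <- labels
  out
}
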