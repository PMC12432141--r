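# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package: dense loops, full sorts, two-pass
# statistics.

# dense 2-D convolution with symmetric (reflective, edge-included) padding
oracle_conv2d_symmetric <- function(img, kern) {
  n <- nrow(img); m <- ncol(img)
  p <- (nrow(kern) - 1) / 2
  reflect <- function(i, len) {
    if (i < 1) 1 - i else if (i > len) 2 * len + 1 - i else i
  }
  out <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      acc <- 0
      for (di in -p:p) {
        for (dj in -p:p) {
          acc <- acc + kern[di + p + 1, dj + p + 1] *
            img[reflect(i + di, n), reflect(j + dj, m)]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# two-pass mean/SD (population) + explicit comparison loop
oracle_background_threshold <- function(img, sd_mult = 5) {
  n <- length(img)
  mu <- sum(img) / n
  s <- sqrt(sum((img - mu)^2) / n)
  thr <- mu + sd_mult * s
  out <- img
  for (i in seq_along(out)) if (out[i] < thr) out[i] <- 0
  out
}

oracle_block_mean <- function(img, block = 2) {
  nb <- nrow(img) / block
  mb <- ncol(img) / block
  out <- matrix(0, nb, mb)
  for (i in seq_len(nb)) {
    for (j in seq_len(mb)) {
      acc <- 0
      for (di in seq_len(block)) {
        for (dj in seq_len(block)) {
          acc <- acc + img[(i - 1) * block + di, (j - 1) * block + dj]
        }
      }
      out[i, j] <- acc / block^2
    }
  }
  out
}

# full sort + hand linear interpolation at rank (n - 1) * q (0-based)
oracle_percentile <- function(x, q) {
  s <- sort(x)
  r <- (length(x) - 1) * q
  lo <- floor(r)
  hi <- ceiling(r)
  s[lo + 1] + (r - lo) * (s[hi + 1] - s[lo + 1])
}

# Mann-Whitney rank AUC with ties counted half (positive = 1)
oracle_rank_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# gaussian weights identical by construction to the documented default
blur_kernel_2d <- function(k = 5, sigma = NULL) {
  if (is.null(sigma)) sigma <- 0.3 * ((k - 1) / 2 - 1) + 0.8
  h <- (k - 1) / 2
  w <- exp(-((-h:h)^2) / (2 * sigma^2))
  w <- w / sum(w)
  outer(w, w)
}
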