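test_that("noise-free, signal-free scene is exactly the background level", {
  spec <- scene_spec(side = 64L, n_signals = 0L, background_mean = 100,
                     background_sd = 0, seed = 3L)
  img <- generate_clean_image(spec)
  expect_true(all(img$image == 100L))
  expect_identical(img$label, "clean")
  expect_null(img$artifact_mask)
})

test_that("generation is bit-identical for a fixed seed", {
  spec <- scene_spec(side = 128L, n_signals = 50L, seed = 7L)
  a <- generate_clean_image(spec)
  b <- generate_clean_image(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$emitters, b$emitters)
})

test_that("invalid scene fields raise validation errors naming the field", {
  expect_error(scene_spec(side = 65L), "even", class = "caeqc_validation_error")
  expect_error(scene_spec(side = 32L), "side", class = "caeqc_validation_error")
  expect_error(scene_spec(background_sd = -1), "background_sd",
               class = "caeqc_validation_error")
  expect_error(scene_spec(signal_amplitude_range = c(5, 1)),
               "signal_amplitude_range", class = "caeqc_validation_error")
  spec <- scene_spec(side = 64L, artifact = artifact_spec("blob"))
  expect_error(generate_clean_image(spec), "artifact",
               class = "caeqc_validation_error")
  expect_error(artifact_spec("vortex"), "unknown artifact kind",
               class = "caeqc_validation_error")
})

test_that("bright-pixel count of a clean scene matches per-emitter footprint bookkeeping", {
  spec <- scene_spec(side = 512L, n_signals = 50L,
                     signal_amplitude_range = c(2000, 8000),
                     background_mean = 500, background_sd = 50, seed = 11L)
  img <- generate_clean_image(spec)
  blurred <- gaussian_blur(img$image)
  thr <- mean(blurred) + 5 * sqrt(mean((blurred - mean(blurred))^2))
  n_bright <- sum(blurred > thr)
  # oracle: re-render each logged emitter alone (direct per-pixel
  # simulation), blur, and count its own above-threshold footprint
  em <- img$emitters
  per_emitter <- integer(nrow(em))
  for (i in seq_len(nrow(em))) {
    single <- caeqc:::render_emitters(matrix(0, spec$side, spec$side),
                                      em$x[i], em$y[i], em$amplitude[i],
                                      spec$psf_sigma)
    per_emitter[i] <- sum(gaussian_blur(single) > (thr - spec$background_mean) / 2)
  }
  # every emitter clears the threshold somewhere, and the bright area
  # cannot exceed the summed footprints (noise flips only footprint edges)
  expect_gte(n_bright, nrow(em))
  expect_lte(n_bright, sum(per_emitter))
})

test_that("a blob on an empty scene stays inside its recorded mask", {
  spec <- scene_spec(side = 128L, n_signals = 0L, background_mean = 0,
                     background_sd = 0, seed = 5L,
                     artifact = artifact_spec("blob", amplitude = 6000,
                                              extent = 40))
  img <- generate_artifact_image(spec)
  expect_identical(img$label, "artifact")
  expect_gte(max(img$image[img$artifact_mask]), 6000 * 0.5)
  expect_true(all(img$image[!img$artifact_mask] == 0L))
})

test_that("a zero-degree scratch is a horizontal band of the requested length", {
  spec <- scene_spec(side = 512L, n_signals = 0L, background_mean = 0,
                     background_sd = 0, seed = 2L,
                     artifact = artifact_spec("scratch", amplitude = 4000,
                                              extent = 300, orientation = 0))
  img <- generate_artifact_image(spec)
  mask <- img$artifact_mask
  cols_hit <- which(colSums(mask) > 0)
  rows_hit <- which(rowSums(mask) > 0)
  expect_gte(length(cols_hit), 299)              # spans >= extent along x
  expect_lte(diff(range(rows_hit)), 5)           # thin in y
  expect_true(all(diff(cols_hit) == 1))          # connected band
})

test_that("agglomerate places round(density * extent^2) emitters, per its log", {
  for (d in c(0.02, 0.05, 0.1)) {
    spec <- scene_spec(side = 256L, n_signals = 0L, seed = 9L,
                       artifact = artifact_spec("agglomerate", amplitude = 5000,
                                                extent = 60, density = d))
    img <- generate_artifact_image(spec)
    expect_identical(nrow(img$artifact_emitters), as.integer(round(d * 60^2)))
    expect_true(any(img$artifact_mask))
  }
})

test_that("every artifact kind yields a non-empty exact mask and label consistency", {
  for (kind in c("blob", "scratch", "streak", "agglomerate")) {
    for (seed in 1:3) {
      spec <- scaled_scene_spec(128L, seed = seed, artifact_kind = kind)
      img <- generate_artifact_image(spec)
      expect_identical(img$label, "artifact")
      expect_true(any(img$artifact_mask), info = kind)
      expect_true(all(img$image >= 0L & img$image <= 16383L), info = kind)
    }
  }
})

test_that("background statistics of signal-free pixels match the scene parameters within 3 SE", {
  spec <- scene_spec(side = 256L, n_signals = 10L, background_mean = 500,
                     background_sd = 50, seed = 21L)
  img <- generate_clean_image(spec)
  # mask out a generous window around each logged emitter
  free <- matrix(TRUE, spec$side, spec$side)
  for (i in seq_len(nrow(img$emitters))) {
    x0 <- round(img$emitters$x[i]); y0 <- round(img$emitters$y[i])
    xs <- max(1, x0 - 8):min(spec$side, x0 + 8)
    ys <- max(1, y0 - 8):min(spec$side, y0 + 8)
    free[ys, xs] <- FALSE
  }
  vals <- img$image[free]
  n <- length(vals)
  se_mean <- 50 / sqrt(n)
  expect_lt(abs(mean(vals) - 500), 3 * se_mean)
  se_sd <- 50 / sqrt(2 * (n - 1))
  expect_lt(abs(sd(vals) - 50), 3 * se_sd + 0.1)  # +0.1 absorbs integer rounding
})

test_that("datasets on disk are reproducible byte for byte", {
  tpl <- scene_spec(side = 64L, n_signals = 5L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- generate_dataset(3L, 2L, tpl, seed = 1L, out_dir = d1)
  m2 <- generate_dataset(3L, 2L, tpl, seed = 1L, out_dir = d2)
  expect_identical(nrow(m1), 5L)
  expect_identical(sum(m1$label == "clean"), 3L)
  expect_identical(m1$label, m2$label)
  expect_identical(m1$seed, m2$seed)
  sums1 <- unname(tools::md5sum(sort(list.files(d1, "\\.tif$", full.names = TRUE))))
  sums2 <- unname(tools::md5sum(sort(list.files(d2, "\\.tif$", full.names = TRUE))))
  expect_identical(sums1, sums2)
  # empty request: empty manifest, no image files
  d3 <- withr::local_tempdir()
  m3 <- generate_dataset(0L, 0L, tpl, seed = 1L, out_dir = d3)
  expect_identical(nrow(m3), 0L)
  expect_length(list.files(d3, "\\.tif$"), 0L)
})

test_that("written images read back within the 14-bit range", {
  tpl <- scene_spec(side = 64L, n_signals = 8L,
                    signal_amplitude_range = c(8000, 16000))
  d <- withr::local_tempdir()
  man <- generate_dataset(1L, 1L, tpl, seed = 4L, out_dir = d)
  for (p in man$path) {
    img <- read_raw_image(p)
    expect_lte(max(img), 16383L)
    expect_gte(min(img), 0L)
  }
})
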