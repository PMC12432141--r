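test_that("default architecture reproduces the published layer shapes", {
  sh <- cae_shapes(cae_config())
  expect_identical(sh$side, c(500L, 500L, 250L, 250L, 125L, 250L, 500L, 500L))
  expect_identical(sh$channels, c(1L, 126L, 126L, 256L, 256L, 256L, 126L, 1L))
  # bottleneck 125 x 125 x 256; output 500 x 500 x 1
  expect_identical(min(sh$side), 125L)
  expect_identical(sh$channels[which.min(sh$side)], 256L)
  expect_identical(unlist(sh[nrow(sh), c("side", "channels")], use.names = FALSE),
                   c(500L, 1L))
})

test_that("scale-reduced configurations keep the same shape arithmetic", {
  sh <- cae_shapes(cae_config(input_side = 128L, filters = c(16L, 32L)))
  expect_identical(min(sh$side), 32L)
  expect_identical(sh$side[nrow(sh)], 128L)
  expect_error(cae_config(input_side = 126L), "divisible",
               class = "caeqc_validation_error")
  # the scale knob shrinks side and filters together
  cfg <- cae_config(scale = 0.2)
  expect_identical(cfg$input_side, 100L)
  expect_identical(cfg$filters, c(25L, 51L))
})

test_that("reconstruction is deterministic, non-negative and shape-preserving", {
  m <- build_cae(cae_config(input_side = 32L, filters = c(4L, 6L), seed = 2L))
  img <- matrix(runif(32 * 32, 0, 0.2), 32, 32)
  r1 <- reconstruct(m, img)
  r2 <- reconstruct(m, img)
  expect_identical(r1, r2)
  expect_identical(dim(r1), dim(img))
  expect_gte(min(r1), 0)
  expect_error(reconstruct(m, matrix(0, 16, 16)), "32",
               class = "caeqc_validation_error")
})

test_that("the all-zero target is learned exactly and history is bookkept", {
  zeros <- replicate(8, matrix(0, 32, 32), simplify = FALSE)
  m <- build_cae(cae_config(input_side = 32L, filters = c(4L, 6L), seed = 1L))
  m <- train_cae(m, zeros, clean_val = zeros[1:2], artifact_val = zeros[3:4],
                 epochs = 3L)
  expect_identical(nrow(m$history), 3L)
  expect_named(m$history, c("epoch", "train_loss", "mse_clean", "pct_diff"))
  expect_equal(m$history$train_loss, rep(0, 3))
  expect_equal(m$history$mse_clean, rep(0, 3))
  expect_equal(m$history$pct_diff, rep(0, 3))  # identical validation sets
  expect_true(all(reconstruct(m, zeros[[1]]) == 0))
  expect_error(train_cae(m, list()), "non-empty",
               class = "caeqc_validation_error")
})

test_that("training on clean synthetic images beats the zero-predictor", {
  raw <- generate_image_set(210L, 4L, scaled_scene_spec(256L), seed = 17L)
  prep <- preprocess_images(raw)
  labels <- attr(prep, "labels")
  m <- build_cae(cae_config(input_side = 128L, filters = c(16L, 32L), seed = 3L))
  m <- train_cae(m, prep[1:200], clean_val = prep[201:210],
                 artifact_val = prep[labels == "artifact"], epochs = 8L)
  # oracle: MSE of predicting the all-zero image for every input
  zero_mse <- mean(vapply(prep[201:210], function(x) mean(x^2), numeric(1)))
  expect_lt(m$history$mse_clean[8], zero_mse)
  expect_lte(m$history$train_loss[8], m$history$train_loss[1])
  expect_identical(nrow(m$history), 8L)
  # artifact-laden validation images reproduce worse throughout
  expect_true(all(m$history$pct_diff > 0))
})

test_that("validation metric arithmetic follows the percent-difference definition", {
  vm <- caeqc:::vm_from_mse(c(0.01, 0.03), c(0.06, 0.02))
  expect_equal(vm$mse_clean, 0.02)
  expect_equal(vm$pct_diff, 100)
  # identity reconstruction: untrained net maps the zero image to itself
  m <- build_cae(cae_config(input_side = 32L, filters = c(4L, 6L)))
  zeros <- list(matrix(0, 32, 32))
  vm0 <- validation_metrics(m, zeros, zeros)
  expect_identical(vm0$mse_clean, 0)
  expect_identical(vm0$pct_diff, 0)
  expect_error(validation_metrics(m, list(), zeros), "non-empty",
               class = "caeqc_validation_error")
})

test_that("artifact-laden fixtures reconstruct worse than clean ones across seeds", {
  wins <- 0L
  for (master in 1:5) {
    raw <- generate_image_set(46L, 6L, scaled_scene_spec(128L),
                              seed = 100L + master)
    prep <- preprocess_images(raw)
    labels <- attr(prep, "labels")
    m <- build_cae(cae_config(input_side = 64L, filters = c(8L, 16L),
                              seed = master))
    m <- train_cae(m, prep[1:40], epochs = 8L)
    held_clean <- prep[41:46]
    held_art <- prep[labels == "artifact"]
    mse_c <- mean(caeqc:::image_mse(m, held_clean))
    mse_a <- mean(caeqc:::image_mse(m, held_art))
    wins <- wins + (mse_a > mse_c)
  }
  expect_gte(wins, 4L)
})

test_that("a saved model reloads with identical behavior", {
  set.seed(7)
  m <- build_cae(cae_config(input_side = 32L, filters = c(4L, 6L), seed = 5L))
  imgs <- replicate(8, matrix(runif(1024, 0, 0.3), 32, 32), simplify = FALSE)
  m <- train_cae(m, imgs, epochs = 2L)
  path <- withr::local_tempfile(fileext = ".rds")
  write_cae(m, path)
  m2 <- read_cae(path)
  img <- matrix(runif(1024, 0, 0.3), 32, 32)
  expect_identical(reconstruct(m2, img), reconstruct(m, img))
  expect_equal(m2$history, m$history)
})

test_that("tidy and glance expose history and architecture summaries", {
  m <- build_cae(cae_config(input_side = 32L, filters = c(4L, 6L)))
  expect_identical(nrow(tidy(m)), 0L)
  g <- glance(m)
  expect_identical(g$bottleneck_side, 8L)
  expect_identical(g$epochs, 0L)
  zeros <- replicate(4, matrix(0, 32, 32), simplify = FALSE)
  m <- train_cae(m, zeros, epochs = 2L)
  expect_identical(nrow(tidy(m)), 2L)
  expect_identical(glance(m)$epochs, 2L)
})
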