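test_that("the t-test is calibrated under the null", {
  set.seed(60)
  hits <- 0L
  for (i in 1:1000) {
    a <- rnorm(30); b <- rnorm(30)
    hits <- hits + (ttest_ire(a, b) > 0.001)
  }
  expect_gte(hits, 990L)
})

test_that("a large shift gives a vanishing p-value, symmetrically", {
  set.seed(61)
  clean <- rep(c(1, 1.1, 0.9, 1.05, 0.95), 10)
  art <- clean + 10
  expect_lt(ttest_ire(clean, art), 1e-10)
  expect_identical(ttest_ire(clean, art), ttest_ire(art, clean))
  expect_error(ttest_ire(rep(1, 5), art), "zero variance",
               class = "caeqc_validation_error")
  expect_error(ttest_ire(1, art), ">= 2", class = "caeqc_validation_error")
})

test_that("perfectly separated groups reach a mean bootstrap AUC of one", {
  set.seed(62)
  clean <- runif(25, 0, 1)
  art <- runif(25, 2, 3)
  expect_equal(bootstrap_auc(clean, art, n_subsets = 200L, seed = 1L), 1)
})

test_that("exchangeable groups give a mean bootstrap AUC near one half", {
  set.seed(63)
  a <- rnorm(100); b <- rnorm(100)
  auc <- bootstrap_auc(a, b, n_subsets = 1000L, seed = 2L, m = 50L)
  expect_lt(abs(auc - 0.5), 0.05)
})

test_that("per-subset AUC equals the Mann-Whitney rank AUC when the slope is positive", {
  set.seed(64)
  for (i in 1:50) {
    x <- c(rnorm(20, 0), rnorm(20, sample(c(0, 1, 3), 1)))
    y <- c(rep(0L, 20), rep(1L, 20))
    fit <- suppressWarnings(stats::glm.fit(cbind(1, x), y,
                                           family = stats::binomial()))
    if (fit$coefficients[2] > 0) {
      got <- caeqc:::roc_auc(caeqc:::logistic_scores(x, y), y)
      expect_equal(got, oracle_rank_auc(x, y), tolerance = 1e-9)
    }
  }
})

test_that("bootstrap AUC is invariant under strictly monotone transforms and seeds reproduce", {
  # separation strong enough that every subset fits a positive slope: the
  # logistic scores are then a monotone transform of the feature and the
  # per-subset AUC is purely rank-based
  set.seed(65)
  clean <- rexp(40); art <- rexp(40) + 2
  a1 <- bootstrap_auc(clean, art, n_subsets = 1000L, seed = 9L)
  a2 <- bootstrap_auc(clean, art, n_subsets = 1000L, seed = 9L)
  expect_identical(a1, a2)  # identical seed, identical to the last bit
  a3 <- bootstrap_auc(log(clean + 1), log(art + 1), n_subsets = 1000L, seed = 9L)
  expect_equal(a1, a3, tolerance = 1e-10)
})

test_that("confusion metrics follow the standard definitions", {
  truth <- c(rep("artifact", 49), rep("clean", 101))
  pred <- c(rep("artifact", 46), rep("clean", 3),
            rep("artifact", 1), rep("clean", 100))
  cm <- confusion_metrics(pred, truth)
  expect_equal(cm$sensitivity, 100 * 46 / 49, tolerance = 1e-12)  # 93.9%
  expect_equal(cm$specificity, 100 * 100 / 101, tolerance = 1e-12) # 99.0%
  expect_equal(cm$accuracy, 100 * 146 / 150, tolerance = 1e-12)    # 97.3%
  expect_equal(round(c(cm$sensitivity, cm$specificity, cm$accuracy), 1),
               c(93.9, 99.0, 97.3))
  # degenerate cases
  all_right <- confusion_metrics(truth, truth)
  expect_equal(c(all_right$sensitivity, all_right$specificity, all_right$accuracy),
               c(100, 100, 100))
  flipped <- ifelse(truth == "clean", "artifact", "clean")
  all_wrong <- confusion_metrics(flipped, truth)
  expect_equal(c(all_wrong$sensitivity, all_wrong$specificity, all_wrong$accuracy),
               c(0, 0, 0))
  no_pos <- confusion_metrics(rep("clean", 5), rep("clean", 5))
  expect_true(is.na(no_pos$sensitivity))
  expect_equal(no_pos$specificity, 100)
})

test_that("confusion metrics are invariant to image order", {
  set.seed(66)
  truth <- sample(c("clean", "artifact"), 60, replace = TRUE)
  pred <- sample(c("clean", "artifact"), 60, replace = TRUE)
  p <- sample.int(60)
  expect_equal(confusion_metrics(pred, truth),
               confusion_metrics(pred[p], truth[p]))
})

test_that("the dataset report composes classification, test and bootstrap", {
  set.seed(67)
  scored <- tibble::tibble(
    image_id = sprintf("img%03d", 1:60),
    ire = c(rnorm(40, 0.01, 0.002), rnorm(20, 0.08, 0.02)),
    label = c(rep("clean", 40), rep("artifact", 20))
  )
  rep1 <- evaluate_dataset(scored, n_subsets = 200L, seed = 3L)
  g <- glance(rep1)
  expect_true(all(c(g$sensitivity, g$specificity, g$accuracy) >= 0 &
                    c(g$sensitivity, g$specificity, g$accuracy) <= 100))
  expect_gte(g$p_value, 0); expect_lte(g$p_value, 1)
  expect_gte(g$mean_auc, 0); expect_lte(g$mean_auc, 1)
  expect_identical(g$n_clean, 40L)
  expect_identical(g$n_artifact, 20L)
  # scale equivariance: doubling IREs and threshold changes nothing
  scored2 <- scored; scored2$ire <- scored2$ire * 2
  rep2 <- evaluate_dataset(scored2, threshold = rep1$threshold_used * 2,
                           n_subsets = 200L, seed = 3L)
  rep1b <- evaluate_dataset(scored, threshold = rep1$threshold_used,
                            n_subsets = 200L, seed = 3L)
  expect_equal(rep2$metrics, rep1b$metrics)
  expect_equal(rep2$p_value, rep1b$p_value, tolerance = 1e-12)
  expect_equal(rep2$mean_auc, rep1b$mean_auc, tolerance = 1e-12)
})

test_that("an all-clean dataset yields full specificity and undefined sensitivity", {
  scored <- tibble::tibble(image_id = sprintf("i%02d", 1:10),
                           ire = runif(10, 0, 0.01),
                           label = rep("clean", 10))
  rep <- evaluate_dataset(scored, threshold = 1, n_subsets = 10L, seed = 1L)
  expect_equal(rep$metrics$specificity, 100)
  expect_true(is.na(rep$metrics$sensitivity))
  scored$label[3] <- NA
  expect_error(evaluate_dataset(scored), "missing",
               class = "caeqc_validation_error")
})
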