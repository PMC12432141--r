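#' Two-tailed t-test between clean and artifact-laden IREs
#'
#' Tests the core premise that artifact-laden images carry higher IREs.
#' Welch's unequal-variance variant is the default because group sizes and
#' spreads differ strongly in screening datasets; the pooled-variance
#' Student test is available by flag.
#'
#' @param clean_ires,artifact_ires numeric vectors, each with at least two
#'   values and nonzero variance.
#' @param var_equal use the pooled-variance (Student) test.
#' @return the two-sided p-value.
#' @export
ttest_ire <- function(clean_ires, artifact_ires, var_equal = FALSE) {
  for (g in list(clean = clean_ires, artifact = artifact_ires)) {
    if (!is.numeric(g) || length(g) < 2L || anyNA(g)) {
      stop_validation("each group needs >= 2 finite IREs")
    }
  }
  if (sd(clean_ires) == 0 || sd(artifact_ires) == 0) {
    stop_validation("degenerate group: zero variance")
  }
  t.test(artifact_ires, clean_ires, var.equal = var_equal)$p.value
}

# trapezoidal ROC AUC from scores (higher score => positive call);
# tie groups collapse to one ROC vertex, the trapezoid rule handles them.
roc_auc <- function(scores, labels) {
  pos <- labels == 1L
  n_pos <- sum(pos); n_neg <- sum(!pos)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; p <- pos[o]
  grp_last <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- c(0, cumsum(p)[grp_last] / n_pos)
  fpr <- c(0, cumsum(!p)[grp_last] / n_neg)
  sum((fpr[-1] - fpr[-length(fpr)]) * (tpr[-1] + tpr[-length(tpr)])) / 2
}

# single-feature logistic regression scores (fitted probabilities)
logistic_scores <- function(x, y) {
  fit <- suppressWarnings(glm.fit(cbind(1, x), y, family = binomial()))
  fit$fitted.values
}

#' Balanced-bootstrap ROC AUC from a one-feature logistic regression
#'
#' Repeatedly draws balanced subsets (`m = min(n_clean, n_artifact)` images
#' per class, with replacement), fits a logistic regression of the class
#' label on the IRE within each subset, builds the ROC curve of its fitted
#' probabilities, and returns the mean AUC over all subsets. Artifact-laden
#' is the positive class.
#'
#' @param clean_ires,artifact_ires numeric IRE vectors (non-empty).
#' @param n_subsets number of bootstrap subsets (default 10000).
#' @param seed optional seed for the resampling stream.
#' @param m per-class subset size; defaults to the minority class size.
#' @return mean AUC over subsets.
#' @export
bootstrap_auc <- function(clean_ires, artifact_ires, n_subsets = 10000L,
                          seed = NULL, m = NULL) {
  if (length(clean_ires) == 0L || length(artifact_ires) == 0L) {
    stop_validation("both groups must be non-empty")
  }
  check_number(n_subsets, "n_subsets", min = 1, integerish = TRUE)
  m <- as.integer(m %||% min(length(clean_ires), length(artifact_ires)))
  check_number(m, "m", min = 1, integerish = TRUE)
  if (!is.null(seed)) set.seed(seed)
  y <- c(rep(0L, m), rep(1L, m))
  aucs <- vapply(seq_len(n_subsets), function(i) {
    x <- c(sample(clean_ires, m, replace = TRUE),
           sample(artifact_ires, m, replace = TRUE))
    roc_auc(logistic_scores(x, y), y)
  }, numeric(1))
  mean(aucs)
}

#' Confusion-matrix metrics with artifact-laden as the positive class
#'
#' @param predicted,truth equal-length label vectors with values
#'   `"clean"` / `"artifact"`.
#' @return one-row tibble with `sensitivity`, `specificity`, `accuracy`
#'   (percentages; `NA` where undefined, e.g. sensitivity without any true
#'   positives in `truth`), plus the four confusion counts.
#' @export
confusion_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop_validation("`predicted` and `truth` must have equal length")
  }
  bad <- setdiff(unique(c(predicted, truth)), c("clean", "artifact"))
  if (length(bad)) {
    stop_validation(sprintf("unknown labels: %s", paste(bad, collapse = ", ")))
  }
  tp <- sum(predicted == "artifact" & truth == "artifact")
  fn <- sum(predicted == "clean" & truth == "artifact")
  tn <- sum(predicted == "clean" & truth == "clean")
  fp <- sum(predicted == "artifact" & truth == "clean")
  tibble(
    sensitivity = if (tp + fn == 0L) NA_real_ else 100 * tp / (tp + fn),
    specificity = if (tn + fp == 0L) NA_real_ else 100 * tn / (tn + fp),
    accuracy = 100 * (tp + tn) / length(truth),
    tp = tp, fn = fn, tn = tn, fp = fp
  )
}

#' Full statistical evaluation of an IRE screening
#'
#' Composes classification at the (given or dataset-adaptive) threshold
#' with the confusion-matrix metrics, the two-tailed t-test and the
#' balanced-bootstrap AUC.
#'
#' @param scored tibble with columns `image_id`, `ire` and a ground-truth
#'   `label` column (`"clean"` / `"artifact"`).
#' @param threshold an [dataset_threshold()], a number, or `NULL` to derive
#'   the adaptive threshold from all IREs in `scored`.
#' @param n_subsets,seed bootstrap parameters, see [bootstrap_auc()].
#' @return a `cae_eval` object; see [glance.cae_eval()].
#' @export
evaluate_dataset <- function(scored, threshold = NULL, n_subsets = 10000L,
                             seed = NULL) {
  if (!is.data.frame(scored) || !all(c("image_id", "ire", "label") %in% names(scored))) {
    stop_validation("`scored` needs columns image_id, ire, label")
  }
  missing <- scored$image_id[is.na(scored$label) | is.na(scored$ire)]
  if (length(missing)) {
    stop_validation(sprintf("missing ire/label for: %s",
                            paste(missing, collapse = ", ")))
  }
  thr <- if (is.null(threshold)) dataset_threshold(scored$ire) else threshold
  thr_val <- if (inherits(thr, "ire_threshold")) thr$threshold else thr
  scored <- classify_ire(scored, thr_val)
  cm <- confusion_metrics(scored$predicted, scored$label)
  clean <- scored$ire[scored$label == "clean"]
  art <- scored$ire[scored$label == "artifact"]
  p_value <- if (length(clean) >= 2L && length(art) >= 2L &&
                 sd(clean) > 0 && sd(art) > 0) {
    ttest_ire(clean, art)
  } else NA_real_
  mean_auc <- if (length(clean) && length(art)) {
    bootstrap_auc(clean, art, n_subsets = n_subsets, seed = seed)
  } else NA_real_
  structure(list(
    classifications = scored,
    threshold = thr,
    threshold_used = thr_val,
    metrics = cm,
    p_value = p_value,
    mean_auc = mean_auc,
    n_clean = length(clean),
    n_artifact = length(art),
    n_subsets = as.integer(n_subsets)
  ), class = "cae_eval")
}

#' @export
print.cae_eval <- function(x, ...) {
  cat(sprintf(paste0(
    "<cae_eval> %d clean + %d artifact images, threshold %.4g\n",
    "  sensitivity %.1f%%, specificity %.1f%%, accuracy %.1f%%\n",
    "  t-test p = %.3g, mean bootstrap AUC = %.4f (%d subsets)\n"),
    x$n_clean, x$n_artifact, x$threshold_used,
    x$metrics$sensitivity, x$metrics$specificity, x$metrics$accuracy,
    x$p_value, x$mean_auc, x$n_subsets))
  invisible(x)
}
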