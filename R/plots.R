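#' Plot the training history of an autoencoder
#'
#' Training loss and the two validation metrics (clean-set MSE and the
#' clean/artifact percent difference) per epoch.
#'
#' @param object a trained `cae`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cae <- function(object, ...) {
  h <- tidy(object)
  long <- tidyr::pivot_longer(h, -"epoch", names_to = "metric",
                              values_to = "value")
  long <- long[!is.na(long$value), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "Autoencoder training history") +
    ggplot2::theme_minimal()
}

#' Plot IRE distributions by class with the screening threshold
#'
#' Jittered IREs per ground-truth (or predicted) label on a log scale,
#' with the dataset-adaptive threshold as a dashed line -- the standard
#' view of how well the score separates artifact-laden images.
#'
#' @param scores tibble with `ire` and a `label` (or `predicted`) column.
#' @param threshold optional [dataset_threshold()] result or number.
#' @return a ggplot.
#' @export
plot_ire_distribution <- function(scores, threshold = NULL) {
  if (!is.data.frame(scores) || !"ire" %in% names(scores)) {
    stop_validation("`scores` needs an `ire` column")
  }
  grp <- scores[["label"]] %||% scores[["predicted"]] %||% "all"
  df <- tibble(ire = scores$ire, group = grp)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$ire)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "image reproduction error (IRE)") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    thr <- if (inherits(threshold, "ire_threshold")) threshold$threshold else threshold
    p <- p + ggplot2::geom_hline(yintercept = thr, linetype = "dashed")
  }
  p
}

#' Plot an evaluation report
#'
#' @param object a `cae_eval`.
#' @param ... unused.
#' @return a ggplot of the per-class IRE distributions with the threshold.
#' @export
autoplot.cae_eval <- function(object, ...) {
  plot_ire_distribution(object$classifications, object$threshold_used) +
    ggplot2::labs(subtitle = sprintf(
      "sensitivity %.1f%%, specificity %.1f%%, accuracy %.1f%%, mean AUC %.3f",
      object$metrics$sensitivity, object$metrics$specificity,
      object$metrics$accuracy, object$mean_auc))
}

#' Display a raw or preprocessed image
#'
#' @param img numeric matrix.
#' @param title optional plot title.
#' @return a ggplot raster.
#' @export
plot_image <- function(img, title = NULL) {
  check_matrix(img)
  df <- tidyr::expand_grid(x = seq_len(ncol(img)), y = seq_len(nrow(img)))
  df$intensity <- as.vector(img)  # column-major: y varies fastest, matching expand_grid's last-fastest order
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_void()
}
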