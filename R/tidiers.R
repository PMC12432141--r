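#' Tidy the training history of an autoencoder
#'
#' @param x a trained `cae`.
#' @param ... unused.
#' @return tibble `(epoch, train_loss, mse_clean, pct_diff)`.
#' @export
tidy.cae <- function(x, ...) {
  if (is.null(x$history)) {
    return(tibble(epoch = integer(), train_loss = numeric(),
                  mse_clean = numeric(), pct_diff = numeric()))
  }
  as_tibble(x$history)
}

#' One-row summary of a (trained) autoencoder
#'
#' @param x a `cae`.
#' @param ... unused.
#' @return tibble with architecture and final-epoch metrics.
#' @export
glance.cae <- function(x, ...) {
  n_par <- sum(vapply(x$layers, function(l) {
    if (is.null(l$W)) 0L else length(l$W) + length(l$b)
  }, integer(1)))
  sh <- cae_shapes(x$config)
  last <- if (!is.null(x$history)) x$history[nrow(x$history), ] else
    tibble(train_loss = NA_real_, mse_clean = NA_real_, pct_diff = NA_real_)
  tibble(input_side = x$config$input_side,
         bottleneck_side = min(sh$side),
         n_parameters = n_par,
         epochs = if (is.null(x$history)) 0L else nrow(x$history),
         train_loss = last$train_loss,
         mse_clean = last$mse_clean,
         pct_diff = last$pct_diff)
}

#' Tidy per-image classifications of an evaluation
#'
#' @param x a `cae_eval` from [evaluate_dataset()].
#' @param ... unused.
#' @return tibble `(image_id, ire, label, predicted)`.
#' @export
tidy.cae_eval <- function(x, ...) as_tibble(x$classifications)

#' One-row summary of an evaluation report
#'
#' @param x a `cae_eval`.
#' @param ... unused.
#' @return tibble with `p_value`, `mean_auc`, `sensitivity`, `specificity`,
#'   `accuracy`, `threshold`, `n_clean`, `n_artifact`.
#' @export
glance.cae_eval <- function(x, ...) {
  tibble(p_value = x$p_value, mean_auc = x$mean_auc,
         sensitivity = x$metrics$sensitivity,
         specificity = x$metrics$specificity,
         accuracy = x$metrics$accuracy,
         threshold = x$threshold_used,
         n_clean = x$n_clean, n_artifact = x$n_artifact)
}

#' Tidy an IRE threshold
#'
#' @param x an `ire_threshold`.
#' @param ... unused.
#' @return one-row tibble `(q25, q50, threshold, n)`.
#' @export
tidy.ire_threshold <- function(x, ...) {
  tibble(q25 = x$q25, q50 = x$q50, threshold = x$threshold, n = x$n)
}
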