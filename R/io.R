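#' Read a raw microscopy image from a 16-bit grayscale TIFF
#'
#' Values are returned as stored integer counts. Multi-channel or
#' float-typed files are rejected; intensities above the nominal 14-bit
#' full scale are rejected unless `allow_high = TRUE`.
#'
#' @param path TIFF (or 16-bit PNG) file path.
#' @param bit_depth nominal sensor bit depth used for range validation.
#' @param allow_high accept intensities above `2^bit_depth - 1` (other
#'   sensors).
#' @return integer matrix of counts.
#' @export
read_raw_image <- function(path, bit_depth = 14L, allow_high = FALSE) {
  if (!file.exists(path)) stop_io(sprintf("file '%s' not found", path))
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    round(png::readPNG(path) * 65535)  # PNG stores integers; undo the [0,1] scaling
  } else {
    tiff::readTIFF(path, as.is = TRUE)
  }
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 1L) img <- img[, , 1L]
    else stop_format(sprintf("'%s' has %d channels; expected single-channel",
                             path, dim(img)[3]))
  }
  if (is.double(img) && any(img != round(img))) {
    stop_format(sprintf("'%s' holds non-integer intensities", path))
  }
  fs <- full_scale(bit_depth)
  if (!allow_high && max(img) > fs) {
    stop_validation(sprintf("'%s': max intensity %d exceeds %d-bit full scale %d",
                            path, max(img), bit_depth, fs))
  }
  storage.mode(img) <- "integer"
  img
}

#' Write a raw image as a single-channel 16-bit TIFF
#'
#' @param img integer-valued matrix of counts in `[0, 2^bit_depth - 1]`.
#' @param path output path.
#' @param bit_depth nominal bit depth used for validation only; storage is
#'   16 bits.
#' @export
write_raw_image <- function(img, path, bit_depth = 14L) {
  check_matrix(img)
  if (any(img < 0) || max(img) > full_scale(bit_depth)) {
    stop_validation("intensities outside the sensor range")
  }
  ok <- try(tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L),
            silent = TRUE)
  if (inherits(ok, "try-error")) stop_io(sprintf("cannot write '%s'", path))
  invisible(path)
}

#' Write / read a preprocessed float image as 32-bit TIFF
#'
#' @param img float matrix in `[0, 1]`.
#' @param path file path.
#' @export
write_float_image <- function(img, path) {
  check_matrix(img)
  if (min(img) < 0 || max(img) > 1) stop_validation("values must be in [0, 1]")
  ok <- try(tiff::writeTIFF(img, path, bits.per.sample = 32L), silent = TRUE)
  if (inherits(ok, "try-error")) stop_io(sprintf("cannot write '%s'", path))
  invisible(path)
}

#' @rdname write_float_image
#' @export
read_float_image <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file '%s' not found", path))
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 1L) img <- img[, , 1L]
    else stop_format(sprintf("'%s' is multi-channel", path))
  }
  img
}

#' Read / write an image manifest CSV
#'
#' A manifest has columns `path` (unique), `label` (one of `clean`,
#' `artifact`, `unknown`) and optionally `seed`.
#'
#' @param path CSV path.
#' @return tibble.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("manifest '%s' not found", path))
  m <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_manifest(m)
}

#' @rdname read_manifest
#' @param manifest manifest tibble.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  readr::write_csv(manifest, path)
  invisible(path)
}

validate_manifest <- function(m) {
  if (!all(c("path", "label") %in% names(m))) {
    stop_format("manifest needs columns `path` and `label`")
  }
  if (anyDuplicated(m$path)) stop_validation("manifest paths must be unique")
  bad <- setdiff(unique(m$label), c("clean", "artifact", "unknown"))
  if (length(bad)) {
    stop_validation(sprintf("unknown manifest labels: %s", paste(bad, collapse = ", ")))
  }
  as_tibble(m)
}

#' Pipeline configuration
#'
#' Bundles the parameters of every stage plus one master seed from which
#' the per-stage random streams (simulation, training, bootstrap) are
#' derived. Round-trips losslessly through YAML.
#'
#' @param preprocess list of [preprocess_image()] parameters.
#' @param cae a [cae_config()].
#' @param ire list with `prob` (IRE percentile) and `multiplier`
#'   (threshold spread multiplier).
#' @param evaluate list with `n_subsets`.
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(preprocess = list(kernel = 5L, sd_mult = 5,
                                              block = 2L, bit_depth = 14L),
                            cae = cae_config(),
                            ire = list(prob = 0.9999, multiplier = 3),
                            evaluate = list(n_subsets = 10000L),
                            seed = 1L) {
  check_number(seed, "seed", integerish = TRUE)
  if (!inherits(cae, "cae_config")) stop_validation("`cae` must be a cae_config()")
  structure(list(preprocess = preprocess, cae = cae, ire = ire,
                 evaluate = evaluate, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$cae <- unclass(x$cae)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config` (for writing).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("config '%s' not found", path))
  x <- yaml::read_yaml(path)
  pipeline_config(preprocess = x$preprocess,
                  cae = do.call(cae_config, x$cae),
                  ire = x$ire, evaluate = x$evaluate, seed = x$seed)
}
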