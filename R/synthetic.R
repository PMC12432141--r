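#' Describe a synthetic sFIDA-like scene
#'
#' A scene is a square 14-bit frame of Gaussian background noise plus sparse
#' sub-resolution point emitters, each rendered as an isotropic Gaussian PSF
#' spot whose peak height is drawn log-uniformly over
#' `signal_amplitude_range` (TIRF point signals vary widely in brightness).
#' An optional [artifact_spec()] adds one artifact structure.
#'
#' @param side image side length in pixels (even, >= 64).
#' @param bit_depth sensor bit depth; intensities are clipped to
#'   `[0, 2^bit_depth - 1]`.
#' @param background_mean,background_sd mean and standard deviation of the
#'   i.i.d. Gaussian background noise, in counts (`background_sd = 0` gives
#'   the noise-free limit).
#' @param n_signals number of point emitters.
#' @param signal_amplitude_range length-2 numeric, min/max PSF peak height
#'   in counts.
#' @param psf_sigma PSF standard deviation in pixels at raw scale.
#' @param artifact an [artifact_spec()] or `NULL` for a clean scene.
#' @param seed integer seed; every draw in the generator flows from it.
#' @param noise one of `"gaussian"` (default) or `"poisson"`; the Poisson
#'   variant uses `background_mean` as the rate and ignores `background_sd`.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(side = 1000L, bit_depth = 14L,
                       background_mean = 500, background_sd = 50,
                       n_signals = 150L,
                       signal_amplitude_range = c(2000, 8000),
                       psf_sigma = 1.0, artifact = NULL, seed = 1L,
                       noise = c("gaussian", "poisson")) {
  noise <- match.arg(noise)
  check_number(side, "side", min = 64, integerish = TRUE)
  if (side %% 2L != 0L) stop_validation("`side` must be even")
  check_number(bit_depth, "bit_depth", min = 1, integerish = TRUE)
  check_number(background_mean, "background_mean", min = 0)
  check_number(background_sd, "background_sd", min = 0)
  check_number(n_signals, "n_signals", min = 0, integerish = TRUE)
  if (length(signal_amplitude_range) != 2L ||
      !all(is.finite(signal_amplitude_range)) ||
      signal_amplitude_range[1] > signal_amplitude_range[2] ||
      signal_amplitude_range[1] <= 0) {
    stop_validation("`signal_amplitude_range` must be positive (min, max) with min <= max")
  }
  check_number(psf_sigma, "psf_sigma", min = 1e-6)
  check_number(seed, "seed", integerish = TRUE)
  if (!is.null(artifact) && !inherits(artifact, "artifact_spec")) {
    stop_validation("`artifact` must be NULL or an artifact_spec()")
  }
  structure(list(
    side = as.integer(side), bit_depth = as.integer(bit_depth),
    background_mean = background_mean, background_sd = background_sd,
    n_signals = as.integer(n_signals),
    signal_amplitude_range = as.numeric(signal_amplitude_range),
    psf_sigma = psf_sigma, artifact = artifact, seed = as.integer(seed),
    noise = noise
  ), class = "scene_spec")
}

#' Density-matched scene spec for a reduced image side
#'
#' Scales the side-1000 reference conditions to a smaller frame: emitter
#' count scales with area (constant signals per pixel), artifact extents
#' scale with the side length, and intensity parameters are unchanged
#' (brightness does not depend on the field of view).
#'
#' @inheritParams scene_spec
#' @param artifact_kind `NULL` for a clean scene, otherwise one of
#'   `"blob"`, `"scratch"`, `"streak"`, `"agglomerate"` rendered with the
#'   reference artifact defaults scaled to `side`.
#' @return a `scene_spec`.
#' @export
scaled_scene_spec <- function(side = 256L, seed = 1L, artifact_kind = NULL) {
  f <- side / 1000
  art <- NULL
  if (!is.null(artifact_kind)) {
    art <- switch(match.arg(artifact_kind, c("blob", "scratch", "streak", "agglomerate")),
      blob = artifact_spec("blob", amplitude = 6000, extent = max(4, round(40 * f))),
      scratch = artifact_spec("scratch", amplitude = 4000,
                              extent = max(8, round(300 * f)), orientation = NULL),
      streak = artifact_spec("streak", amplitude = 3000,
                             extent = max(8, round(200 * f)), orientation = NULL),
      agglomerate = artifact_spec("agglomerate", amplitude = 5000,
                                  extent = max(8, round(80 * f)), density = 0.05)
    )
  }
  scene_spec(side = side, n_signals = max(1L, round(150 * f^2)),
             artifact = art, seed = seed)
}

#' Describe an artifact to inject into a scene
#'
#' The four kinds span the qualitative artifact classes seen on real plates:
#' `blob` (a bright extended smooth structure, e.g. glue or autofluorescent
#' contamination), `scratch` (a hard-edged line across the plate), `streak`
#' (a softer, tapered motion streak) and `agglomerate` (a dense cluster of
#' individually authentic-looking point signals).
#'
#' @param kind artifact class.
#' @param amplitude peak added intensity in counts (> 0).
#' @param extent characteristic size in pixels (>= 2): blob diameter,
#'   scratch/streak length, agglomerate box side.
#' @param density agglomerate only: emitters per pixel^2 of the extent box;
#'   `round(density * extent^2)` emitters are placed.
#' @param orientation scratch/streak only: angle in degrees from the x axis;
#'   `NULL` draws one uniformly.
#' @param width scratch/streak cross-section scale in pixels.
#' @return an `artifact_spec` list.
#' @export
artifact_spec <- function(kind = c("blob", "scratch", "streak", "agglomerate"),
                          amplitude = 6000, extent = 40, density = 0.05,
                          orientation = NULL, width = 3) {
  if (is.character(kind) && length(kind) == 1L &&
      !kind %in% c("blob", "scratch", "streak", "agglomerate")) {
    stop_validation(sprintf("unknown artifact kind '%s'", kind))
  }
  kind <- match.arg(kind)
  check_number(amplitude, "amplitude", min = 1e-9)
  check_number(extent, "extent", min = 2)
  check_number(density, "density", min = 0)
  check_number(width, "width", min = 0.5)
  if (!is.null(orientation)) check_number(orientation, "orientation")
  structure(list(kind = kind, amplitude = amplitude, extent = extent,
                 density = density, orientation = orientation, width = width),
            class = "artifact_spec")
}

full_scale <- function(bit_depth) 2^bit_depth - 1

# render point emitters (peak-height parameterization) into `scene`,
# truncating each Gaussian spot at a 4-sigma window so the altered-pixel set
# is exact. Returns the scene plus an emitter log (x, y, amplitude).
render_emitters <- function(scene, x, y, amp, sigma) {
  side <- nrow(scene)
  r <- ceiling(4 * sigma)
  for (i in seq_along(x)) {
    x0 <- x[i]; y0 <- y[i]
    cx <- round(x0); cy <- round(y0)
    xs <- max(1L, cx - r):min(side, cx + r)
    ys <- max(1L, cy - r):min(side, cy + r)
    gx <- exp(-((xs - x0)^2) / (2 * sigma^2))
    gy <- exp(-((ys - y0)^2) / (2 * sigma^2))
    scene[ys, xs] <- scene[ys, xs] + amp[i] * outer(gy, gx)
  }
  scene
}

draw_emitters <- function(n, side, amp_range) {
  # positions continuous and uniform over the frame; amplitudes log-uniform
  x <- runif(n, 0.5, side + 0.5)
  y <- runif(n, 0.5, side + 0.5)
  amp <- exp(runif(n, log(amp_range[1]), log(amp_range[2])))
  list(x = x, y = y, amplitude = amp)
}

render_artifact <- function(side, art, psf_sigma) {
  add <- matrix(0, side, side)
  log <- NULL
  if (art$kind == "blob") {
    cx <- runif(1, art$extent / 2, side - art$extent / 2 + 1)
    cy <- runif(1, art$extent / 2, side - art$extent / 2 + 1)
    xs <- seq_len(side)
    r2 <- outer((xs - cy)^2, (xs - cx)^2, `+`)
    sig <- art$extent / 4
    g <- art$amplitude * exp(-r2 / (2 * sig^2))
    g[r2 > (art$extent / 2)^2] <- 0  # hard truncation => exact mask
    add <- add + g
  } else if (art$kind %in% c("scratch", "streak")) {
    theta <- (art$orientation %||% runif(1, 0, 180)) * pi / 180
    ux <- cos(theta); uy <- sin(theta)
    margin <- art$extent / 2
    cx <- runif(1, max(1, side / 2 - margin), min(side, side / 2 + margin))
    cy <- runif(1, side * 0.25, side * 0.75)
    xs <- seq_len(side)
    # signed coordinates along/across the segment through (cx, cy)
    X <- matrix(xs, side, side, byrow = TRUE) - cx
    Y <- matrix(xs, side, side) - cy
    along <- X * ux + Y * uy
    across <- -X * uy + Y * ux
    inside <- abs(along) <= art$extent / 2
    if (art$kind == "scratch") {
      prof <- inside & (abs(across) <= art$width / 2)
      add <- add + art$amplitude * prof
    } else {
      sw <- art$width * 1.5
      prof <- exp(-across^2 / (2 * sw^2))
      prof[!inside | abs(across) > 2 * sw] <- 0
      taper <- 0.3 + 0.7 * (along + art$extent / 2) / art$extent  # motion ramp
      add <- add + art$amplitude * prof * pmax(taper, 0) * inside
    }
  } else if (art$kind == "agglomerate") {
    n_e <- round(art$density * art$extent^2)
    x0 <- runif(1, 1, max(1, side - art$extent))
    y0 <- runif(1, 1, max(1, side - art$extent))
    ex <- runif(n_e, x0, x0 + art$extent)
    ey <- runif(n_e, y0, y0 + art$extent)
    amp <- exp(runif(n_e, log(art$amplitude / 4), log(art$amplitude)))
    add <- render_emitters(add, ex, ey, amp, psf_sigma)
    log <- tibble(x = ex, y = ey, amplitude = amp)
  }
  list(add = add, emitters = log)
}

finish_image <- function(noiseless, spec) {
  side <- spec$side
  if (spec$noise == "poisson") {
    img <- matrix(stats::rpois(side * side, lambda = noiseless + spec$background_mean),
                  side, side)
  } else {
    img <- noiseless + spec$background_mean +
      matrix(rnorm(side * side, 0, spec$background_sd), side, side)
    img <- round(img)
  }
  img <- pmin(pmax(img, 0), full_scale(spec$bit_depth))
  storage.mode(img) <- "integer"
  img
}

#' Generate an artifact-free synthetic image
#'
#' Draws emitter positions/amplitudes, renders PSF spots on a noiseless
#' scene, then adds clipped, rounded background noise. Deterministic for a
#' fixed `spec$seed`.
#'
#' @param spec a [scene_spec()] with `artifact = NULL`.
#' @return a `labeled_image` list: `image` (integer matrix), `label`
#'   (`"clean"`), `artifact_mask` (`NULL`), `emitters` (log tibble), `spec`.
#' @export
generate_clean_image <- function(spec) {
  if (!inherits(spec, "scene_spec")) stop_validation("`spec` must be a scene_spec()")
  if (!is.null(spec$artifact)) {
    stop_validation("`spec$artifact` must be absent for a clean image")
  }
  set.seed(spec$seed)
  em <- draw_emitters(spec$n_signals, spec$side, spec$signal_amplitude_range)
  scene <- matrix(0, spec$side, spec$side)
  scene <- render_emitters(scene, em$x, em$y, em$amplitude, spec$psf_sigma)
  img <- finish_image(scene, spec)
  structure(list(image = img, label = "clean", artifact_mask = NULL,
                 emitters = tibble(x = em$x, y = em$y, amplitude = em$amplitude),
                 spec = spec),
            class = "labeled_image")
}

#' Generate an artifact-laden synthetic image
#'
#' The clean scene is rendered first, the artifact is added to the noiseless
#' scene (so the recorded mask of altered pixels is exact), and noise is
#' applied last.
#'
#' @param spec a [scene_spec()] with an [artifact_spec()] attached.
#' @return a `labeled_image` with `label = "artifact"` and a logical
#'   `artifact_mask` matrix marking every pixel whose noiseless intensity
#'   the artifact changed.
#' @export
generate_artifact_image <- function(spec) {
  if (!inherits(spec, "scene_spec")) stop_validation("`spec` must be a scene_spec()")
  if (is.null(spec$artifact)) stop_validation("`spec$artifact` must be present")
  set.seed(spec$seed)
  em <- draw_emitters(spec$n_signals, spec$side, spec$signal_amplitude_range)
  scene <- matrix(0, spec$side, spec$side)
  scene <- render_emitters(scene, em$x, em$y, em$amplitude, spec$psf_sigma)
  art <- render_artifact(spec$side, spec$artifact, spec$psf_sigma)
  mask <- art$add > 0
  if (!any(mask)) stop_validation("artifact mask is empty; increase amplitude/extent")
  img <- finish_image(scene + art$add, spec)
  structure(list(image = img, label = "artifact", artifact_mask = mask,
                 emitters = tibble(x = em$x, y = em$y, amplitude = em$amplitude),
                 artifact_emitters = art$emitters, spec = spec),
            class = "labeled_image")
}

#' @export
print.labeled_image <- function(x, ...) {
  cat(sprintf("<labeled_image> %dx%d, label = %s, %d emitters\n",
              nrow(x$image), ncol(x$image), x$label, nrow(x$emitters)))
  invisible(x)
}

# deterministic per-image seed stream from a master seed (kept < 2^31 - 1)
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) * 48271 + i * 16807) %% 2147483647)
}

#' Generate a labeled set of synthetic images in memory
#'
#' @param n_clean,n_artifact image counts (>= 0).
#' @param spec_template a [scene_spec()] used for every image; per-image
#'   seeds are derived deterministically from `seed`.
#' @param seed master seed.
#' @param artifact_kinds artifact classes cycled over the artifact images.
#' @return a list of `labeled_image`s with attribute `manifest`, a tibble
#'   `(image_id, label, seed, artifact_kind)`.
#' @export
generate_image_set <- function(n_clean, n_artifact, spec_template = scene_spec(),
                               seed = 1L,
                               artifact_kinds = c("blob", "scratch", "streak",
                                                  "agglomerate")) {
  check_number(n_clean, "n_clean", min = 0, integerish = TRUE)
  check_number(n_artifact, "n_artifact", min = 0, integerish = TRUE)
  if (!inherits(spec_template, "scene_spec")) {
    stop_validation("`spec_template` must be a scene_spec()")
  }
  n <- n_clean + n_artifact
  imgs <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- derive_seed(seed, i)
    if (i <= n_clean) {
      sp <- spec_template
      sp$artifact <- NULL
      sp$seed <- s
      imgs[[i]] <- generate_clean_image(sp)
      rows[[i]] <- tibble(image_id = sprintf("img_%04d", i), label = "clean",
                          seed = s, artifact_kind = NA_character_)
    } else {
      kind <- artifact_kinds[((i - n_clean - 1L) %% length(artifact_kinds)) + 1L]
      sp <- spec_template
      # per-kind scaled default unless the template pins one artifact
      sp$artifact <- spec_template$artifact %||%
        scaled_scene_spec(spec_template$side, artifact_kind = kind)$artifact
      sp$seed <- s
      imgs[[i]] <- generate_artifact_image(sp)
      rows[[i]] <- tibble(image_id = sprintf("img_%04d", i), label = "artifact",
                          seed = s, artifact_kind = sp$artifact$kind)
    }
  }
  manifest <- dplyr::bind_rows(rows)
  attr(imgs, "manifest") <- manifest
  imgs
}

#' Generate a synthetic dataset on disk
#'
#' Writes each image as a single-channel 16-bit TIFF plus a CSV manifest
#' (`path,label,seed`) and a YAML serialization of the scene template.
#' Identical calls produce byte-identical files.
#'
#' @inheritParams generate_image_set
#' @param out_dir output directory (created if needed).
#' @return the manifest tibble (with `path` relative to `out_dir`'s parent),
#'   invisibly also written to `manifest.csv`.
#' @export
generate_dataset <- function(n_clean, n_artifact, spec_template = scene_spec(),
                             seed = 1L, out_dir,
                             artifact_kinds = c("blob", "scratch", "streak",
                                                 "agglomerate")) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_io(sprintf("cannot create output directory '%s'", out_dir))
  }
  if (file.access(out_dir, 2) != 0) {
    stop_io(sprintf("output directory '%s' is not writable", out_dir))
  }
  imgs <- generate_image_set(n_clean, n_artifact, spec_template, seed,
                             artifact_kinds)
  manifest <- attr(imgs, "manifest")
  if (nrow(manifest) == 0L) {
    manifest <- tibble(path = character(), label = character(), seed = integer())
    readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
    return(invisible(manifest))
  }
  manifest$path <- file.path(out_dir, paste0(manifest$image_id, ".tif"))
  for (i in seq_along(imgs)) {
    write_raw_image(imgs[[i]]$image, manifest$path[i],
                    bit_depth = spec_template$bit_depth)
  }
  out <- manifest[, c("path", "label", "seed")]
  readr::write_csv(out, file.path(out_dir, "manifest.csv"))
  tpl <- spec_template
  tpl$artifact <- if (is.null(tpl$artifact)) NULL else unclass(tpl$artifact)
  yaml::write_yaml(unclass(tpl), file.path(out_dir, "scene_spec.yaml"))
  invisible(out)
}
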