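#' Run the full artifact-screening pipeline
#'
#' Ties all stages together: read (or take) raw images, preprocess, train
#' the autoencoder on the clean training set, compute IREs for the scoring
#' set, derive the dataset-adaptive threshold, classify, and evaluate
#' against the ground-truth labels. An image is either used for model
#' training or scored -- never both -- and training images must be labeled
#' clean; both rules are enforced before any computation. Every stage
#' writes its outputs plus a JSON sidecar of the parameters used so a
#' report can be traced to its exact configuration.
#'
#' @param manifest tibble with columns `path` (or `image_id` for in-memory
#'   input), `label` and `role` (`"train"` / `"score"`).
#' @param config a [pipeline_config()].
#' @param out_dir output directory; created if needed.
#' @param images optional named list of raw matrices keyed by
#'   `manifest$path`, bypassing disk reads (used by the simulator-driven
#'   workflow and tests).
#' @param threshold optional precomputed assay-specific threshold; `NULL`
#'   derives the adaptive threshold from the scored IREs.
#' @param verbose log stage progress to stderr.
#' @return a list with `model`, `scores` (tibble with `ire`, `predicted`),
#'   `threshold`, and `report` (a `cae_eval`).
#' @export
run_pipeline <- function(manifest, config = pipeline_config(), out_dir = NULL,
                         images = NULL, threshold = NULL, verbose = TRUE) {
  if (!is.data.frame(manifest) || !all(c("label", "role") %in% names(manifest))) {
    stop_validation("`manifest` needs columns label and role")
  }
  if (!"path" %in% names(manifest) && !"image_id" %in% names(manifest)) {
    stop_validation("`manifest` needs a `path` or `image_id` column")
  }
  key <- if ("path" %in% names(manifest)) manifest$path else manifest$image_id
  bad_role <- setdiff(unique(manifest$role), c("train", "score"))
  if (length(bad_role)) {
    stop_validation(sprintf("unknown roles: %s", paste(bad_role, collapse = ", ")))
  }
  train_keys <- key[manifest$role == "train"]
  score_keys <- key[manifest$role == "score"]
  if (length(train_keys) == 0L) stop_validation("no training images in manifest")
  if (length(score_keys) == 0L) stop_validation("no scoring images in manifest")
  overlap <- intersect(train_keys, score_keys)
  if (length(overlap)) {
    stop_validation(sprintf("images in both training and scoring roles: %s",
                            paste(overlap, collapse = ", ")))
  }
  not_clean <- manifest$role == "train" & manifest$label != "clean"
  if (any(not_clean)) {
    stop_validation(sprintf("training images must be labeled clean: %s",
                            paste(key[not_clean], collapse = ", ")))
  }
  log_stage <- function(...) if (verbose) message(sprintf(...))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }

  get_raw <- function(k) {
    if (!is.null(images)) images[[k]] else
      read_raw_image(k, bit_depth = config$preprocess$bit_depth %||% 14L)
  }
  log_stage("[preprocess] %d images", nrow(manifest))
  pp <- config$preprocess
  prep <- lapply(key, function(k) {
    do.call(preprocess_image, c(list(raw = get_raw(k)), pp))
  })
  names(prep) <- key

  log_stage("[train] %d clean images, %d epochs",
            length(train_keys), config$cae$epochs)
  cae_cfg <- config$cae
  cae_cfg$seed <- derive_seed(config$seed, 2L)
  model <- build_cae(cae_cfg)
  model <- train_cae(model, prep[train_keys], verbose = verbose)

  log_stage("[score] %d images", length(score_keys))
  scores <- ire_scores(model, prep[score_keys], image_id = score_keys,
                       prob = config$ire$prob %||% 0.9999)
  scores$label <- manifest$label[match(score_keys, key)]

  thr <- threshold %||% dataset_threshold(scores$ire,
                                          multiplier = config$ire$multiplier %||% 3)
  scores <- classify_ire(scores, thr)
  log_stage("[threshold] %.4g", if (inherits(thr, "ire_threshold")) thr$threshold else thr)

  report <- NULL
  if (all(scores$label %in% c("clean", "artifact"))) {
    report <- evaluate_dataset(scores, threshold = thr,
                               n_subsets = config$evaluate$n_subsets %||% 10000L,
                               seed = derive_seed(config$seed, 3L))
  }

  if (!is.null(out_dir)) {
    readr::write_csv(scores[, c("image_id", "ire")], file.path(out_dir, "ires.csv"))
    readr::write_csv(scores[, c("image_id", "ire", "predicted")],
                     file.path(out_dir, "labels.csv"))
    readr::write_csv(model$history, file.path(out_dir, "history.csv"))
    write_cae(model, file.path(out_dir, "model.rds"))
    if (!is.null(report)) {
      jsonlite::write_json(glance(report), file.path(out_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    cfg_out <- list(config = unclass_deep(config),
                    n_train = length(train_keys), n_score = length(score_keys))
    jsonlite::write_json(cfg_out, file.path(out_dir, "params.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(model = model, scores = scores, threshold = thr, report = report)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Simulate, split and screen one synthetic experiment
#'
#' Convenience wrapper for desk-scale experiments: generates
#' `n_train + n_val_clean + n_val_artifact` synthetic images from a scene
#' template, trains the autoencoder on the clean training images, and
#' scores/evaluates the held-out clean and artifact-laden images.
#'
#' @param n_train clean training images.
#' @param n_val_clean,n_val_artifact held-out clean / artifact-laden images.
#' @param spec_template [scene_spec()] for the simulator.
#' @param config [pipeline_config()]; its master seed drives simulation,
#'   training and bootstrap substreams.
#' @param verbose log progress.
#' @return as [run_pipeline()].
#' @export
run_synthetic_experiment <- function(n_train = 200L, n_val_clean = 50L,
                                     n_val_artifact = 50L,
                                     spec_template = scaled_scene_spec(256L),
                                     config = NULL, verbose = TRUE) {
  config <- config %||% pipeline_config(
    cae = cae_config(input_side = as.integer(spec_template$side / 2),
                     filters = c(16L, 32L)),
    evaluate = list(n_subsets = 1000L)
  )
  imgs <- generate_image_set(n_val_clean + n_train, n_val_artifact,
                             spec_template, seed = derive_seed(config$seed, 1L))
  man <- attr(imgs, "manifest")
  # first n_train clean images train the model; the rest are scored
  man$role <- c(rep("train", n_train),
                rep("score", n_val_clean + n_val_artifact))
  raw <- lapply(imgs, function(x) x$image)
  names(raw) <- man$image_id
  run_pipeline(man, config = config, images = raw, verbose = verbose)
}
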