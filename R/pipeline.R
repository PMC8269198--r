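#' Experiment configuration
#'
#' Bundles a model family, a training configuration and a segmentation
#' strategy into one runnable experiment. The strategy must be consistent
#' across model, loss and extraction: the instance strategy forces an
#' embedding head on the model.
#'
#' @param model A [model_config()].
#' @param train A [train_config()].
#' @param evaluation Options for scoring: `list(threshold = 0.5, bandwidth =
#'   NULL, min_size = 10)`; `bandwidth = NULL` uses the training pull margin.
#' @param output_dir Optional directory for artifacts (checkpoint, logs,
#'   report CSV); `NULL` writes nothing.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(model, train,
                              evaluation = list(threshold = 0.5,
                                                bandwidth = NULL,
                                                min_size = 10L),
                              output_dir = NULL) {
  stopifnot(inherits(model, "model_config"), inherits(train, "train_config"))
  if (train$strategy == "instance" && is.null(model$embedding_dim))
    model$embedding_dim <- 8L
  if (train$strategy != "instance") model$embedding_dim <- NULL
  structure(list(model = model, train = train, evaluation = evaluation,
                 output_dir = output_dir),
            class = "experiment_config")
}

#' Run one train/evaluate experiment
#'
#' Trains on the training split, model-selects on the validation split, and
#' reports IoU/SBD mean and standard deviation on the held-out test split
#' only. A leakage guard aborts if any patient appears in more than one
#' split. When `output_dir` is set, the checkpoint, training log, split
#' manifest and a one-row report CSV are written there.
#'
#' @param config An [experiment_config()].
#' @param split A patient-level split from [split_by_patient()].
#' @return `list(report = metric_report, model, log)`.
#' @export
run_experiment <- function(config, split) {
  stopifnot(inherits(config, "experiment_config"))
  check_split_leakage(split)
  set.seed(config$train$seed)
  model <- build_model(config$model)
  fit <- train(model, split$train, split$val, config$train)
  report <- evaluate_model(fit$model, split$test, config)
  report$model <- config$model$family
  report$strategy <- config$train$strategy
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    save_checkpoint(fit$model, file.path(config$output_dir, "checkpoint.rds"))
    write_training_log(fit$log, file.path(config$output_dir, "training_log.csv"))
    write_split_manifest(split, file.path(config$output_dir, "split_manifest.csv"))
    write_metric_report_csv(report, file.path(config$output_dir, "report.csv"))
    write_metric_report_json(report, file.path(config$output_dir, "report.json"))
  }
  list(report = report, model = fit$model, log = fit$log)
}

check_split_leakage <- function(split) {
  pids <- lapply(split[c("train", "val", "test")], function(part)
    unique(vapply(part, function(s) s$patient_id, character(1))))
  for (a in 1:2) for (b in (a + 1):3) {
    dup <- intersect(pids[[a]], pids[[b]])
    if (length(dup))
      stop("run_experiment: patient(s) ", paste(dup, collapse = ", "),
           " appear in more than one split — aborting (leakage guard)")
  }
  invisible(TRUE)
}

#' Score a trained model on a set of samples
#'
#' Predicts every sample (with tiled stitching for tiles larger than the
#' training patch) and aggregates IoU/SBD with [evaluate_dataset()].
#'
#' @param model A trained `tam_model`.
#' @param samples List of samples with ground truth.
#' @param config The [experiment_config()] (for strategy and evaluation
#'   options); alternatively a plain list with `train$strategy` and
#'   `evaluation`.
#' @return A `metric_report`.
#' @export
evaluate_model <- function(model, samples, config) {
  ev <- config$evaluation
  bw <- if (is.null(ev$bandwidth)) config$train$disc_params$delta_v else ev$bandwidth
  pairs <- lapply(samples, function(s) {
    pred <- predict_instances(model, s$image, strategy = config$train$strategy,
                              patch_size = config$train$patch_size,
                              threshold = ev$threshold, bandwidth = bw,
                              min_size = ev$min_size,
                              spatial_clean = isTRUE(ev$spatial_clean))
    list(predicted = pred, truth = s$truth, id = s$id)
  })
  evaluate_dataset(pairs)
}

#' Predict an instance mask for one image
#'
#' Images no larger than `patch_size` are processed in a single pass. Larger
#' images are processed as overlapping `patch_size` tiles (default 32 px
#' overlap) whose class scores and embeddings are stitched by centered
#' cropping, so every interior pixel is predicted by the tile in which it is
#' most central; clustering then runs once on the stitched full-tile fields,
#' keeping instances that straddle tile seams whole.
#'
#' @param model A trained `tam_model`.
#' @param image `H x W x 3` array.
#' @param strategy Segmentation strategy used in training.
#' @param patch_size Network input size (default 224).
#' @param overlap Tile overlap in pixels (default 32).
#' @param threshold,bandwidth,min_size,spatial_clean Extraction options as
#'   in [extract_instances()].
#' @return A [label_mask()].
#' @export
predict_instances <- function(model, image,
                              strategy = c("vanilla", "weighted", "instance"),
                              patch_size = 224L, overlap = 32L, threshold = 0.5,
                              bandwidth = disc_loss_params()$delta_v,
                              min_size = 10L, spatial_clean = FALSE) {
  strategy <- match.arg(strategy)
  out <- predict_fields(model, image, patch_size, overlap)
  extract_instances(out, strategy, threshold, bandwidth, min_size, spatial_clean)
}

# Raw stitched network fields (class scores + embeddings) for an image of any
# size compatible with the network stride.
predict_fields <- function(model, image, patch_size = 224L, overlap = 32L) {
  h <- dim(image)[1]; w <- dim(image)[2]
  if (h <= patch_size && w <= patch_size)
    return(model_forward(model, image))
  stride <- patch_size - overlap
  starts <- function(total) {
    if (total <= patch_size) return(1L)
    s <- seq(1L, total - patch_size + 1L, by = stride)
    if (s[length(s)] != total - patch_size + 1L) s <- c(s, total - patch_size + 1L)
    s
  }
  ys <- starts(h); xs <- starts(w)
  cs <- array(0, c(h, w, model$config$num_classes))
  emb <- if (!is.null(model$nodes$embedding))
    array(0, c(h, w, model$config$embedding_dim)) else NULL
  # centre distance of the owning tile, per pixel: a pixel is written by the
  # tile whose centre is nearest (centred-crop blending)
  best <- matrix(Inf, h, w)
  for (y0 in ys) for (x0 in xs) {
    yr <- y0:(y0 + patch_size - 1L); xr <- x0:(x0 + patch_size - 1L)
    o <- model_forward(model, image[yr, xr, , drop = FALSE])
    cy <- y0 + (patch_size - 1) / 2; cx <- x0 + (patch_size - 1) / 2
    dist <- outer((yr - cy)^2, (xr - cx)^2, `+`)
    take <- dist < best[yr, xr]
    best[yr, xr][take] <- dist[take]
    for (c in seq_len(dim(cs)[3])) {
      plane <- cs[yr, xr, c]; plane[take] <- o$class_scores[, , c][take]
      cs[yr, xr, c] <- plane
    }
    if (!is.null(emb)) for (c in seq_len(dim(emb)[3])) {
      plane <- emb[yr, xr, c]; plane[take] <- o$embeddings[, , c][take]
      emb[yr, xr, c] <- plane
    }
  }
  list(class_scores = cs, embeddings = emb)
}

#' Predict masks and morphometry for image files
#'
#' Loads a checkpoint, predicts each image, writes 16-bit label masks next to
#' the requested output directory and one CSV of per-instance statistics.
#'
#' @param checkpoint Path to a checkpoint written by [save_checkpoint()].
#' @param image_paths Character vector of PNG/TIFF image files.
#' @param output_dir Output directory.
#' @param strategy Strategy the checkpoint was trained with; must be
#'   consistent with the checkpoint (instance requires an embedding head).
#' @param um_per_px Optional calibration for areas in square micrometres.
#' @param ... Passed to [predict_instances()].
#' @return Invisibly, the combined instance-statistics data.frame.
#' @export
predict_files <- function(checkpoint, image_paths, output_dir,
                          strategy = c("vanilla", "weighted", "instance"),
                          um_per_px = NULL, ...) {
  strategy <- match.arg(strategy)
  model <- load_checkpoint(checkpoint)
  if (strategy == "instance" && is.null(model$nodes$embedding))
    stop("predict_files: checkpoint has no embedding head but strategy is 'instance'")
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  all_stats <- list()
  for (path in image_paths) {
    img <- load_rgb_image(path)
    mask <- predict_instances(model, img, strategy = strategy, ...)
    base <- tools::file_path_sans_ext(basename(path))
    write_label_mask(mask, file.path(output_dir, paste0(base, "_mask.tif")))
    st <- instance_stats(mask, um_per_px = um_per_px)
    if (nrow(st)) st$image <- base
    all_stats[[base]] <- st
  }
  stats <- do.call(rbind, all_stats)
  utils::write.csv(stats, file.path(output_dir, "instance_stats.csv"),
                   row.names = FALSE)
  invisible(stats)
}

#' Read an RGB image file into an `H x W x 3` array
#' @param path PNG or TIFF file.
#' @return Numeric array in \[0,1\], rows = image rows.
#' @export
load_rgb_image <- function(path) {
  m <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) tiff::readTIFF(path)
       else png::readPNG(path)
  if (length(dim(m)) == 2L) m <- array(rep(m, 3), c(dim(m), 3))
  array(m[, , 1:3], c(dim(m)[1], dim(m)[2], 3))
}

#' Write an RGB array as PNG
#' @param image `H x W x 3` array in \[0,1\].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
save_rgb_image <- function(image, path) {
  png::writePNG(image, path)
  invisible(path)
}

#' Run the full model-by-strategy experiment grid
#'
#' Crosses the requested model families with the requested strategies (the
#' full 3x3 grid by default) on one shared patient-level split, and collects
#' one report row per experiment.
#'
#' @param families Character vector of model families.
#' @param strategies Character vector of strategies.
#' @param split A [split_by_patient()] result.
#' @param model_args,train_args Named lists of overrides passed to
#'   [model_config()] / [train_config()].
#' @param output_dir Optional artifact directory (one subdirectory per
#'   experiment).
#' @return `list(reports = list of metric_report, table = data.frame)`.
#' @export
run_grid <- function(families = c("unet", "segnet", "deeplabv3"),
                     strategies = c("vanilla", "weighted", "instance"),
                     split, model_args = list(), train_args = list(),
                     output_dir = NULL) {
  reports <- list()
  for (fam in families) for (strat in strategies) {
    mc <- do.call(model_config, utils::modifyList(list(family = fam), model_args))
    tc <- do.call(train_config, utils::modifyList(list(strategy = strat), train_args))
    od <- if (!is.null(output_dir)) file.path(output_dir, paste(fam, strat, sep = "_"))
          else NULL
    res <- run_experiment(experiment_config(mc, tc, output_dir = od), split)
    reports[[paste(fam, strat, sep = "_")]] <- res$report
  }
  table <- do.call(rbind, lapply(reports, function(r)
    data.frame(model = r$model, strategy = r$strategy,
               iou_mean = round(r$iou_mean, 4), iou_stdev = round(r$iou_stdev, 4),
               sbd_mean = round(r$sbd_mean, 4), sbd_stdev = round(r$sbd_stdev, 4),
               stringsAsFactors = FALSE)))
  rownames(table) <- NULL
  if (!is.null(output_dir))
    utils::write.csv(table, file.path(output_dir, "grid_report.csv"), row.names = FALSE)
  list(reports = reports, table = table)
}
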