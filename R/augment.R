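#' Augmentation configuration
#'
#' Controls the aggressive augmentation applied to training samples:
#' geometric transforms (rotation at any angle; scaling, shear and elastic
#' warp with morphological factors drawn from `morph_factor_range`) and
#' photometric transforms (per-channel color jitter, contrast, hue and
#' exposure changes applied to the image only). Each enabled transform fires
#' independently with probability `prob` per sample.
#'
#' @param morph_factor_range Interval for the random morphological factor
#'   (default `c(0.8, 1.3)`).
#' @param rotation,scaling,shear,warp,color_jitter,contrast,hue,exposure
#'   Enable flags per transform.
#' @param prob Per-transform application probability (default 0.5).
#' @param jitter_amount Photometric jitter amplitude as a fraction (default
#'   0.1, i.e. roughly ±10% for color/contrast/exposure and ±0.1 of the hue
#'   circle scaled down to ±0.036 turns).
#' @param rng_seed Optional seed; if `NULL` the current RNG stream is used.
#' @return An `augmentation_config` list.
#' @export
augmentation_config <- function(morph_factor_range = c(0.8, 1.3),
                                rotation = TRUE, scaling = TRUE, shear = TRUE,
                                warp = TRUE, color_jitter = TRUE, contrast = TRUE,
                                hue = TRUE, exposure = TRUE,
                                prob = 0.5, jitter_amount = 0.1, rng_seed = NULL) {
  stopifnot(length(morph_factor_range) == 2L, morph_factor_range[1] > 0,
            morph_factor_range[1] < morph_factor_range[2],
            prob >= 0, prob <= 1, jitter_amount >= 0)
  structure(list(morph_factor_range = morph_factor_range, rotation = rotation,
                 scaling = scaling, shear = shear, warp = warp,
                 color_jitter = color_jitter, contrast = contrast, hue = hue,
                 exposure = exposure, prob = prob, jitter_amount = jitter_amount,
                 rng_seed = rng_seed),
            class = "augmentation_config")
}

# Reflect 1-based coordinates into [1, n] (mirror boundary).
reflect_coord <- function(x, n) {
  if (n == 1L) return(rep(1, length(x)))
  period <- 2 * (n - 1)
  x <- (x - 1) %% period
  x <- ifelse(x > (n - 1), period - x, x)
  x + 1
}

#' Augment a sample
#'
#' Applies one identical geometric transform to the image (bilinear,
#' reflect-padded), the label mask (nearest-neighbour, zero/background
#' padded — no fractional instance ids can arise) and the weight map
#' (bilinear, reflect-padded), followed by photometric transforms on the
#' image alone. Deterministic given the RNG state (or `config$rng_seed`).
#' If the transform empties a non-empty mask the draw is retried a bounded
#' number of times, after which the sample is returned unchanged with a
#' warning.
#'
#' @param sample `list(image, truth, weight_map = NULL, ...)` as produced by
#'   [generate_dataset()].
#' @param config An [augmentation_config()].
#' @param max_retry Retry budget for all-background outcomes (default 5).
#' @return The augmented sample (same structure).
#' @export
augment <- function(sample, config = augmentation_config(), max_retry = 5L) {
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  had_fg <- any(sample$truth > 0L)
  for (attempt in seq_len(max_retry + 1L)) {
    out <- augment_once(sample, config)
    if (!had_fg || any(out$truth > 0L)) return(out)
  }
  warning("augment: transform emptied the mask after retries; returning sample unchanged")
  sample
}

augment_once <- function(sample, config) {
  img <- sample$image
  h <- dim(img)[1]; w <- dim(img)[2]
  fire <- function(enabled) isTRUE(enabled) && stats::runif(1) < config$prob
  morph <- function() stats::runif(1, config$morph_factor_range[1], config$morph_factor_range[2])

  theta <- if (fire(config$rotation)) stats::runif(1, 0, 2 * pi) else 0
  s <- if (fire(config$scaling)) morph() else 1
  shear_k <- if (fire(config$shear)) morph() - 1 else 0
  do_warp <- fire(config$warp)

  geo <- !(theta == 0 && s == 1 && shear_k == 0 && !do_warp)
  if (geo) {
    warp_amp <- if (do_warp)
      0.04 * min(h, w) * (morph() - config$morph_factor_range[1]) /
        diff(config$morph_factor_range) else 0
    sample <- geometric_transform(sample, theta = theta, scale = s,
                                  shear = shear_k, warp_amp = warp_amp)
    img <- sample$image
  }

  ja <- config$jitter_amount
  if (fire(config$color_jitter)) {
    f <- stats::runif(3, 1 - ja, 1 + ja)
    for (c in 1:3) img[, , c] <- img[, , c] * f[c]
  }
  if (fire(config$contrast)) {
    f <- stats::runif(1, 1 - ja, 1 + ja)
    img <- (img - 0.5) * f + 0.5
  }
  if (fire(config$hue)) {
    shift <- stats::runif(1, -0.36 * ja, 0.36 * ja)  # turns of the hue circle
    rgb <- matrix(pmin(1, pmax(0, img)), ncol = 3)
    hsv <- grDevices::rgb2hsv(t(rgb), maxColorValue = 1)
    hsv[1, ] <- (hsv[1, ] + shift) %% 1
    img <- array(t(grDevices::col2rgb(grDevices::hsv(hsv[1, ], hsv[2, ], hsv[3, ])) / 255),
                 dim(img))
  }
  if (fire(config$exposure)) {
    f <- stats::runif(1, 1 - ja, 1 + ja)
    img <- img * f
  }
  sample$image <- array(pmin(1, pmax(0, img)), dim(img))
  sample
}

#' Apply one geometric transform congruently to image, labels and weights
#'
#' Backward-maps every output pixel through the inverse of a centre-anchored
#' rotation/scale/shear (plus an optional smooth sinusoidal warp field) and
#' resamples: bilinear with mirror padding for the image and weight map,
#' nearest-neighbour with background fill for the label mask.
#'
#' @param sample A sample list.
#' @param theta Rotation angle in radians (counter-clockwise).
#' @param scale Isotropic scale factor.
#' @param shear Shear coefficient (0 = none).
#' @param warp_amp Elastic warp displacement amplitude in pixels (0 = none).
#' @return The transformed sample.
#' @export
geometric_transform <- function(sample, theta = 0, scale = 1, shear = 0,
                                warp_amp = 0) {
  img <- sample$image
  h <- dim(img)[1]; w <- dim(img)[2]
  A <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2) %*%
       matrix(c(scale, 0, shear * scale, scale), 2, 2)
  Ainv <- solve(A)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- matrix(rep(seq_len(h), w), h, w) - cy
  xx <- matrix(rep(seq_len(w), each = h), h, w) - cx
  sy <- cy + Ainv[1, 1] * yy + Ainv[1, 2] * xx
  sx <- cx + Ainv[2, 1] * yy + Ainv[2, 2] * xx
  if (warp_amp > 0) {
    fy <- stats::runif(2, 1, 3); ph <- stats::runif(4, 0, 2 * pi)
    gy <- seq_len(h) / h; gx <- seq_len(w) / w
    sy <- sy + warp_amp * outer(sin(2 * pi * fy[1] * gy + ph[1]), cos(2 * pi * gx + ph[2]))
    sx <- sx + warp_amp * outer(cos(2 * pi * fy[2] * gy + ph[3]), sin(2 * pi * gx + ph[4]))
  }
  ry <- matrix(reflect_coord(sy, h), h, w)
  rx <- matrix(reflect_coord(sx, w), h, w)
  sample$image <- .cpp_resample_map(img, ry, rx, TRUE, 0)
  truth_px <- .cpp_resample_map(array(as.numeric(sample$truth), c(h, w, 1)),
                                matrix(sy, h, w), matrix(sx, h, w), FALSE, 0)
  sample$truth <- label_mask(matrix(truth_px, h, w), canonical = FALSE)
  if (!is.null(sample$weight_map)) {
    wmattr <- attributes(sample$weight_map)
    wmp <- .cpp_resample_map(array(unclass(sample$weight_map), c(h, w, 1)), ry, rx, TRUE, 1)
    wm <- matrix(wmp, h, w)
    attributes(wm) <- utils::modifyList(wmattr, list(dim = c(h, w)))
    sample$weight_map <- wm
  }
  sample
}

#' Extract a random square patch
#'
#' Crops an axis-aligned `size x size` patch at a uniformly random valid
#' offset, applied congruently to image, label mask and weight map.
#'
#' @param sample A sample list.
#' @param size Patch side in pixels (default 224).
#' @return The cropped sample.
#' @export
sample_patch <- function(sample, size = 224L) {
  h <- dim(sample$image)[1]; w <- dim(sample$image)[2]
  if (h < size || w < size)
    stop(sprintf("sample_patch: tile %dx%d smaller than patch %d", h, w, size))
  y0 <- sample.int(h - size + 1L, 1L)
  x0 <- sample.int(w - size + 1L, 1L)
  ys <- y0:(y0 + size - 1L); xs <- x0:(x0 + size - 1L)
  sample$image <- sample$image[ys, xs, , drop = FALSE]
  sample$truth <- label_mask(unclass(sample$truth)[ys, xs], canonical = FALSE)
  if (!is.null(sample$weight_map)) {
    wmattr <- attributes(sample$weight_map)
    wm <- unclass(sample$weight_map)[ys, xs]
    attributes(wm) <- utils::modifyList(wmattr, list(dim = c(size, size)))
    sample$weight_map <- wm
  }
  sample
}

#' Patient-level train/validation/test split
#'
#' Assigns whole patients — never individual tiles — to the three partitions,
#' so no patient's material leaks across splits. Validation and test receive
#' `round(fraction * n_patients)` patients each; the remainder goes to
#' training. Deterministic given `seed`.
#'
#' @param samples List of samples, each carrying a non-empty `patient_id`.
#' @param fractions Train/validation/test fractions summing to 1
#'   (default `c(0.70, 0.15, 0.15)`).
#' @param seed Integer seed for the patient shuffle.
#' @return `list(train =, val =, test =)` of sample lists, with a
#'   `manifest` attribute (data.frame: patient_id, sample_id, partition).
#' @export
split_by_patient <- function(samples, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  pid <- vapply(samples, function(s) {
    if (is.null(s$patient_id) || !nzchar(s$patient_id))
      stop("split_by_patient: every sample needs a non-empty patient_id")
    s$patient_id
  }, character(1))
  if (abs(sum(fractions) - 1) > 1e-8) stop("split_by_patient: fractions must sum to 1")
  patients <- unique(pid)
  if (length(patients) < 3L) stop("split_by_patient: need at least 3 patients")
  set.seed(seed)
  shuffled <- base::sample(patients)
  n <- length(patients)
  n_val <- round(fractions[2] * n)
  n_test <- round(fractions[3] * n)
  n_train <- n - n_val - n_test
  assign <- rep(c("train", "val", "test"), c(n_train, n_val, n_test))
  names(assign) <- shuffled
  part <- assign[pid]
  manifest <- data.frame(patient_id = pid,
                         sample_id = vapply(samples, function(s)
                           if (!is.null(s$id)) s$id else "", character(1)),
                         partition = unname(part), stringsAsFactors = FALSE)
  out <- list(train = samples[part == "train"],
              val = samples[part == "val"],
              test = samples[part == "test"])
  attr(out, "manifest") <- manifest
  out
}

#' Write a split manifest CSV
#' @param split Result of [split_by_patient()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_split_manifest <- function(split, path) {
  utils::write.csv(attr(split, "manifest"), path, row.names = FALSE)
  invisible(path)
}
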