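#' Per-pixel loss weight maps for gap emphasis and edge de-emphasis
#'
#' Builds the per-pixel penalty map used by the weighted-semantic strategy.
#' Background pixels lying in a narrow corridor between two distinct cells —
#' i.e. whose Euclidean distances to the nearest pixels of their two nearest
#' *distinct* instances are both strictly below `proximity_px` — receive
#' `gap_weight * base_weight`, pushing the model to keep such gaps as
#' background and thereby separate adjacent cells. Foreground pixels on the
#' cell boundary (8-adjacent to background, band depth `edge_depth_px`)
#' receive `edge_weight * base_weight`, discounting the blurry, imperfectly
#' annotated cell rims. Everything else gets `base_weight`.
#'
#' Per-instance distances are computed with exact Euclidean distance
#' transforms (one per instance), so the map depends only on instance
#' geometry, never on id values.
#'
#' @param truth A [label_mask()] with ground-truth instances (0 allowed).
#' @param proximity_px Gap rule distance threshold in pixels (default 10).
#' @param gap_weight Multiplier for corridor pixels (default 3: roughly three
#'   times the base penalty).
#' @param edge_weight Multiplier for cell-boundary pixels (default 0.5).
#' @param base_weight Baseline multiplier (default 1).
#' @param edge_depth_px Depth of the de-emphasized boundary band (default 1).
#' @param edge_on_background Apply the edge discount also to background pixels
#'   8-adjacent to foreground (default `FALSE`: foreground rim only).
#' @return A `weight_map`: a positive numeric matrix with the parameters
#'   attached as attributes.
#' @export
compute_weight_map <- function(truth, proximity_px = 10L, gap_weight = 3.0,
                               edge_weight = 0.5, base_weight = 1.0,
                               edge_depth_px = 1L, edge_on_background = FALSE) {
  if (proximity_px < 1L) stop("compute_weight_map: proximity_px must be >= 1")
  if (gap_weight <= 0 || edge_weight <= 0 || base_weight <= 0)
    stop("compute_weight_map: weights must be positive")
  truth <- relabel_canonical(truth)
  h <- nrow(truth); w <- ncol(truth)
  wm <- matrix(base_weight, h, w)
  m <- n_instances(truth)

  if (m >= 1L) {
    fg <- unclass(truth) > 0L
    edge <- boundary_band(truth, edge_depth_px, include_background = edge_on_background)
    wm[edge] <- base_weight * edge_weight
    if (m >= 2L) {
      # distance of every pixel to each instance's pixel set
      d1 <- matrix(Inf, h, w)  # nearest instance distance
      d2 <- matrix(Inf, h, w)  # second-nearest (distinct instance) distance
      for (k in seq_len(m)) {
        dk <- instance_distance(truth, k)
        closer <- dk < d1
        d2[closer] <- d1[closer]
        d1[closer] <- dk[closer]
        mid <- !closer & (dk < d2)
        d2[mid] <- dk[mid]
      }
      gap <- !fg & (d1 < proximity_px) & (d2 < proximity_px)
      wm[gap] <- base_weight * gap_weight
    }
  }
  structure(wm,
            base_weight = base_weight, gap_weight = gap_weight,
            edge_weight = edge_weight, proximity_px = proximity_px,
            class = c("weight_map", "matrix", "array"))
}

# Exact Euclidean distance from every pixel to the pixel set of instance k
# (0 on the instance itself). EBImage::distmap measures distance to the
# nearest zero-valued pixel, so feed it the instance's complement.
instance_distance <- function(mask, k) {
  comp <- matrix(1, nrow(mask), ncol(mask))
  comp[mask == k] <- 0
  d <- EBImage::imageData(EBImage::distmap(EBImage::Image(comp), metric = "euclidean"))
  matrix(d, nrow(mask), ncol(mask))
}

# Pixels within `depth` of the foreground/background interface under
# 8-connectivity: the foreground rim is fg minus fg eroded `depth` times with
# a 3x3 box, the optional background rim its dual. Off-grid counts as
# background, so cells clipped by the tile border keep a rim there.
boundary_band <- function(mask, depth = 1L, include_background = FALSE) {
  fg <- unclass(mask) > 0L
  eroded <- fg
  for (i in seq_len(depth)) eroded <- erode8(eroded)
  band <- fg & !eroded
  if (include_background) {
    dil <- fg
    for (i in seq_len(depth)) dil <- dilate8(dil)
    band <- band | (!fg & dil)
  }
  band
}

# 3x3 box erosion/dilation with off-grid treated as background.
erode8 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  p <- matrix(FALSE, h + 2L, w + 2L)
  p[2:(h + 1), 2:(w + 1)] <- m
  out <- m
  for (dy in -1:1) for (dx in -1:1)
    out <- out & p[(2 + dy):(h + 1 + dy), (2 + dx):(w + 1 + dx)]
  out
}

dilate8 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  p <- matrix(FALSE, h + 2L, w + 2L)
  p[2:(h + 1), 2:(w + 1)] <- m
  out <- m
  for (dy in -1:1) for (dx in -1:1)
    out <- out | p[(2 + dy):(h + 1 + dy), (2 + dx):(w + 1 + dx)]
  out
}

#' Weighted pixel-wise cross-entropy
#'
#' Mean over pixels of `weight(x) * CE(x)` where `CE` is the two-class
#' cross-entropy between the per-pixel class scores and the binary truth.
#' With all weights equal to 1 this reduces exactly to the unweighted pixel
#' cross-entropy; the loss is linear in the weights.
#'
#' @param class_scores An `H x W x 2` array of unnormalized scores (logits)
#'   over (background, foreground), or an `H x W` matrix of foreground
#'   probabilities in (0, 1).
#' @param truth A [binary_mask()] (or label mask, binarized).
#' @param weights A weight map matrix (default all 1).
#' @return Non-negative scalar loss.
#' @export
weighted_pixel_cross_entropy <- function(class_scores, truth, weights = NULL) {
  t <- as_fg(truth)
  if (is.null(weights)) weights <- matrix(1, nrow(t), ncol(t))
  if (!all(is.finite(class_scores))) stop("weighted_pixel_cross_entropy: non-finite scores")
  if (length(dim(class_scores)) == 3L) {
    if (!identical(dim(class_scores)[1:2], dim(t)))
      stop("weighted_pixel_cross_entropy: score/truth shape mismatch")
    p <- softmax_fg(class_scores)
  } else {
    check_same_shape(class_scores, t, "scores and truth")
    p <- class_scores
  }
  check_same_shape(weights, t, "weights and truth")
  eps <- 1e-12
  ce <- -(t * log(pmax(p, eps)) + (1 - t) * log(pmax(1 - p, eps)))
  mean(unclass(weights) * ce)
}

# Foreground probability from a 2-channel logit array (channel 2 = foreground).
softmax_fg <- function(scores) {
  a <- scores[, , 1L]; b <- scores[, , 2L]
  m <- pmax(a, b)
  eb <- exp(b - m)
  eb / (exp(a - m) + eb)
}
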