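#' Binary foreground masks
#'
#' A `binary_mask` is a 2-D logical matrix where `TRUE` marks foreground
#' (macrophage) pixels and `FALSE` marks background. Empty masks are allowed.
#'
#' @param pixels A logical matrix, or anything coercible with non-zero pixels
#'   treated as foreground.
#' @return An object of class `binary_mask` (a logical matrix).
#' @examples
#' m <- binary_mask(matrix(c(0, 1, 1, 0), 2, 2))
#' sum(m)
#' @export
binary_mask <- function(pixels) {
  if (is.null(dim(pixels)) || length(dim(pixels)) != 2L)
    stop("binary_mask: `pixels` must be a 2-D matrix")
  m <- matrix(as.logical(pixels != 0), nrow(pixels), ncol(pixels))
  if (anyNA(m)) stop("binary_mask: NA pixels are not allowed")
  structure(m, class = c("binary_mask", class(m)))
}

#' Integer instance-label masks
#'
#' A `label_mask` is a 2-D non-negative integer matrix: 0 marks background and
#' each positive integer identifies one instance (one cell). Instances are
#' pairwise disjoint by construction since each pixel holds a single id.
#'
#' @param pixels A numeric or integer matrix of non-negative labels.
#' @param canonical If `TRUE` (default), relabel ids to the contiguous range
#'   `1..M` in raster discovery order via [relabel_canonical()].
#' @return An object of class `label_mask` (an integer matrix).
#' @seealso [relabel_canonical()], [n_instances()]
#' @export
label_mask <- function(pixels, canonical = TRUE) {
  if (is.null(dim(pixels)) || length(dim(pixels)) != 2L)
    stop("label_mask: `pixels` must be a 2-D matrix")
  if (anyNA(pixels)) stop("label_mask: NA pixels are not allowed")
  if (any(pixels < 0)) stop("label_mask: negative instance labels are not allowed")
  m <- matrix(as.integer(round(pixels)), nrow(pixels), ncol(pixels))
  m <- structure(m, class = c("label_mask", class(m)))
  if (canonical) m <- relabel_canonical(m) else m
}

#' Relabel instance ids to the contiguous range 1..M
#'
#' Remaps the positive labels of a mask to `1..M`, preserving the pixel
#' partition exactly. Ids are assigned in order of first appearance in
#' column-major (raster) order. All instance-level metrics are invariant
#' under this operation.
#'
#' @param mask A [label_mask()] or a non-negative integer matrix.
#' @return A canonical `label_mask`.
#' @export
relabel_canonical <- function(mask) {
  if (any(mask < 0)) stop("relabel_canonical: negative labels")
  m <- matrix(as.integer(round(mask)), nrow(mask), ncol(mask))
  ids <- unique(m[m > 0L])
  if (length(ids)) {
    lut <- integer(max(ids))
    lut[ids] <- seq_along(ids)
    pos <- m > 0L
    m[pos] <- lut[m[pos]]
  }
  structure(m, class = c("label_mask", "matrix", "array"))
}

#' Number of instances in a label mask
#' @param mask A [label_mask()].
#' @return Integer count of distinct positive labels.
#' @export
n_instances <- function(mask) length(unique(mask[mask > 0L]))

#' Collapse a label mask to its binary foreground
#' @param mask A [label_mask()].
#' @return A [binary_mask()]: any instance pixel becomes foreground.
#' @export
binarize <- function(mask) binary_mask(mask > 0L)

#' Split a label mask into per-instance pixel index sets
#'
#' @param mask A [label_mask()].
#' @return Named list mapping each instance id to the integer vector of its
#'   (column-major) linear pixel indices.
#' @keywords internal
instance_pixel_sets <- function(mask) {
  pos <- which(mask > 0L)
  split(pos, mask[pos])
}

check_same_shape <- function(a, b, what = "masks") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s have different shapes: %s vs %s", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  invisible(TRUE)
}

#' Read and write label masks as 16-bit images
#'
#' Label masks are persisted as single-channel 16-bit TIFF (or PNG); binary
#' masks as 8-bit PNG with foreground = 255. Weight maps use 32-bit float
#' TIFF. Values survive the round trip exactly for labels up to 65535.
#'
#' @param mask A [label_mask()] / [binary_mask()] / weight-map matrix.
#' @param path Output file; extension selects the container (.tif/.tiff/.png).
#' @return `write_*` return `path` invisibly; `read_*` return the mask object.
#' @name mask_io
NULL

#' @rdname mask_io
#' @export
write_label_mask <- function(mask, path) {
  if (max(mask) > 65535L) stop("write_label_mask: more than 65535 instances")
  m <- matrix(as.numeric(mask) / 65535, nrow(mask), ncol(mask))
  tiff::writeTIFF(m, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname mask_io
#' @export
read_label_mask <- function(path) {
  m <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::readTIFF(path)
  } else png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  label_mask(round(m * 65535), canonical = FALSE)
}

#' @rdname mask_io
#' @export
write_binary_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname mask_io
#' @export
read_binary_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  binary_mask(m > 0.5)
}

#' @rdname mask_io
#' @export
write_weight_map <- function(mask, path) {
  # float TIFF storage is defined on [0,1]; weights are stored divided by a
  # fixed power-of-two scale (64), exact in float32 for dyadic multipliers
  if (max(mask) > 64) stop("write_weight_map: weights above the storage scale (64)")
  tiff::writeTIFF(matrix(as.numeric(mask) / 64, nrow(mask), ncol(mask)), path,
                  bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname mask_io
#' @export
read_weight_map <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  matrix(m * 64, nrow(m), ncol(m))
}
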