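#' Specification for a synthetic stained-cell tile
#'
#' Parameters of the deterministic generator that emulates CD163/DAB-stained
#' macrophages — brown, irregular, blurry-edged blobs of heterogeneous area,
#' some touching or adjacent — over a blue hematoxylin-like hepatocyte
#' background with darker nuclei. The ground-truth instance mask records the
#' generating partition exactly, so every downstream module can be exercised
#' and scored without clinical slides.
#'
#' @param height,width Tile size in pixels (default 512x512; 1920x1080 and
#'   small 128x128 desk tiles are equally supported).
#' @param n_cells Number of cells to place.
#' @param cell_radius_range Interval of mean cell radii in pixels (default
#'   10–40, covering roughly the 20–80 px diameter regime of the source data).
#' @param bimodal_radii If `TRUE`, draw radii from a small/large mixture
#'   (lower and upper quarter of the range) instead of uniformly — an S/L-TAM
#'   style area mix.
#' @param touching_pair_fraction Fraction of cells placed as adjacent pairs
#'   whose silhouettes touch (gap 0–2 px) or overlap, resolved to distinct
#'   adjacent instances.
#' @param min_gap_px Minimum boundary gap between non-paired cells.
#' @param stain_foreground,stain_background RGB triplets in \[0,1\]: DAB-brown
#'   cell stain and hematoxylin blue-gray background.
#' @param edge_blur_sigma Gaussian blur (px) applied to the rendered image —
#'   not the mask — emulating blurry cell edges.
#' @param noise_sigma Additive Gaussian pixel noise standard deviation.
#' @param seed Integer seed; the whole tile is a pure function of the spec.
#' @return A `synthetic_tile_spec` list.
#' @export
synthetic_tile_spec <- function(height = 512L, width = 512L, n_cells = 25L,
                                cell_radius_range = c(10, 40), bimodal_radii = FALSE,
                                touching_pair_fraction = 0.25, min_gap_px = 6L,
                                stain_foreground = c(0.52, 0.33, 0.16),
                                stain_background = c(0.72, 0.74, 0.86),
                                edge_blur_sigma = 1.0, noise_sigma = 0.03,
                                seed = 1L) {
  stopifnot(height >= 32, width >= 32, n_cells >= 0,
            length(cell_radius_range) == 2L, cell_radius_range[1] >= 2,
            cell_radius_range[2] >= cell_radius_range[1],
            touching_pair_fraction >= 0, touching_pair_fraction <= 1,
            min_gap_px >= 0,
            all(stain_foreground >= 0 & stain_foreground <= 1),
            all(stain_background >= 0 & stain_background <= 1))
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_cells = as.integer(n_cells),
                 cell_radius_range = as.numeric(cell_radius_range),
                 bimodal_radii = isTRUE(bimodal_radii),
                 touching_pair_fraction = touching_pair_fraction,
                 min_gap_px = as.integer(min_gap_px),
                 stain_foreground = stain_foreground,
                 stain_background = stain_background,
                 edge_blur_sigma = edge_blur_sigma, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "synthetic_tile_spec")
}

# One irregular cell silhouette: an ellipse whose radius is modulated by a
# truncated Fourier series (harmonics 2..5), rasterized into a logical patch.
# Returns the patch, its top-left offset and its maximum radius.
random_cell_shape <- function(mean_radius) {
  ecc <- stats::runif(1, 0.72, 1)           # axis ratio
  rx <- mean_radius / sqrt(ecc); ry <- mean_radius * sqrt(ecc)
  rot <- stats::runif(1, 0, pi)
  amp <- stats::runif(4, 0, 0.10) * c(1, 0.8, 0.6, 0.4)
  phs <- stats::runif(4, 0, 2 * pi)
  rmax <- max(rx, ry) * (1 + sum(amp)) + 1
  half <- ceiling(rmax)
  n <- 2L * half + 1L
  yy <- matrix(rep(-half:half, n), n, n)
  xx <- t(yy)
  xr <- cos(rot) * xx + sin(rot) * yy
  yr <- -sin(rot) * xx + cos(rot) * yy
  theta <- atan2(yr, xr)
  base <- rx * ry / sqrt((ry * cos(theta))^2 + (rx * sin(theta))^2)
  pert <- 1 + amp[1] * cos(2 * theta + phs[1]) + amp[2] * cos(3 * theta + phs[2]) +
    amp[3] * cos(4 * theta + phs[3]) + amp[4] * cos(5 * theta + phs[4])
  rad <- sqrt(xr^2 + yr^2)
  norm <- rad / pmax(base * pert, 1e-6)      # < 1 inside the silhouette
  list(norm = norm, half = half, rmax = rmax)
}

# Directional support of a rasterized shape: the largest projection of any
# silhouette pixel offset onto the (row, col) unit vector u.
shape_support <- function(shape, u) {
  px <- which(shape$norm < 1, arr.ind = TRUE) - (shape$half + 1L)
  max(px[, 1] * u[1] + px[, 2] * u[2])
}

shape_pixels <- function(shape, centre) {
  px <- which(shape$norm < 1, arr.ind = TRUE) - (shape$half + 1L)
  cbind(px[, 1] + centre[1], px[, 2] + centre[2])
}

# Move the partner cell along the pair axis until the closest silhouette
# pixel-centre distance equals target_gap + 1 (= target_gap background
# pixels between the cells). NULL if a few nudges cannot achieve it.
adjust_pair_gap <- function(s1, c1, s2, c2, target_gap, phi) {
  p1 <- shape_pixels(s1, c1)
  want <- target_gap + 1L
  for (step in 1:8) {
    p2 <- shape_pixels(s2, c2)
    dmin <- sqrt(min(outer(p1[, 1], p2[, 1], "-")^2 + outer(p1[, 2], p2[, 2], "-")^2))
    if (abs(dmin - want) < 0.5) return(c2)
    dir <- if (dmin > want) -1 else 1
    c2 <- c(round(c2[1] + dir * sin(phi)), round(c2[2] + dir * cos(phi)))
  }
  NULL
}

draw_radius <- function(spec) {
  r <- spec$cell_radius_range
  if (spec$bimodal_radii) {
    lo <- c(r[1], r[1] + 0.25 * diff(r))
    hi <- c(r[2] - 0.25 * diff(r), r[2])
    if (stats::runif(1) < 0.5) stats::runif(1, lo[1], lo[2]) else stats::runif(1, hi[1], hi[2])
  } else stats::runif(1, r[1], r[2])
}

#' Generate one synthetic tile with its exact instance mask
#'
#' Cells are placed with bounded rejection sampling: the requested fraction
#' forms adjacent/touching pairs (centers at roughly the sum of radii, gaps
#' 0–2 px, overlaps resolved by assigning contested pixels to the cell whose
#' normalized radial coordinate is smaller, so instances never share pixels),
#' remaining cells keep at least `min_gap_px` of background between
#' silhouettes. The image gets per-cell stain-tone jitter, foamy lighter
#' inclusions inside large cells, nucleus-like darker blue blobs in the
#' background, Gaussian edge blur and pixel noise. Fully deterministic given
#' the spec (including its seed).
#'
#' @param spec A [synthetic_tile_spec()].
#' @return `list(image = H x W x 3 array in [0,1], truth = label_mask)`.
#' @export
generate_tile <- function(spec) {
  stopifnot(inherits(spec, "synthetic_tile_spec"))
  set.seed(spec$seed)
  h <- spec$height; w <- spec$width
  lab <- matrix(0L, h, w)
  norm_coord <- matrix(Inf, h, w)  # normalized radial coordinate of owner cell

  place <- function(cy, cx, shape, id) {
    half <- shape$half
    ys <- max(1L, cy - half):min(h, cy + half)
    xs <- max(1L, cx - half):min(w, cx + half)
    if (!length(ys) || !length(xs)) return(invisible(NULL))
    py <- ys - (cy - half) + 1L
    px <- xs - (cx - half) + 1L
    sub <- shape$norm[py, px, drop = FALSE]
    cur_n <- norm_coord[ys, xs, drop = FALSE]
    cur_l <- lab[ys, xs, drop = FALSE]
    take <- sub < 1 & sub < cur_n
    cur_n[take] <- sub[take]
    cur_l[take] <- id
    norm_coord[ys, xs] <<- cur_n
    lab[ys, xs] <<- cur_l
    invisible(NULL)
  }

  n_pairs <- round(spec$touching_pair_fraction * spec$n_cells / 2)
  n_single <- spec$n_cells - 2L * n_pairs
  centers <- matrix(numeric(0), 0, 2)
  radii <- numeric(0)
  next_id <- 1L
  bridge_pairs <- list()  # thin-gap pairs whose corridor is stained over
  margin <- function(r) max(2, ceiling(0.3 * r))

  ok_placement <- function(cy, cx, rmax, slack) {
    if (!nrow(centers)) return(TRUE)
    d <- sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2)
    all(d >= radii + rmax + slack)
  }

  try_place_group <- function(k_cells, paired) {
    for (attempt in 1:300) {
      r1 <- draw_radius(spec)
      s1 <- random_cell_shape(r1)
      # cells may clip the tile border (as in real tiles); keep the centre
      # far enough inside that a meaningful fragment stays visible
      cy1 <- round(stats::runif(1, 0.4 * r1, h - 0.4 * r1))
      cx1 <- round(stats::runif(1, 0.4 * r1, w - 0.4 * r1))
      if (!ok_placement(cy1, cx1, s1$rmax, spec$min_gap_px)) next
      if (!paired) {
        place(cy1, cx1, s1, next_id)
        centers <<- rbind(centers, c(cy1, cx1)); radii <<- c(radii, s1$rmax)
        next_id <<- next_id + 1L
        return(TRUE)
      }
      r2 <- draw_radius(spec)
      s2 <- random_cell_shape(r2)
      phi <- stats::runif(1, 0, 2 * pi)
      # half the pairs overlap/touch outright (separable only by instance
      # methods); half keep a thin 1-2 px annotation-style gap (the corridor
      # substrate of the per-pixel penalty rule)
      target_gap <- sample(c(-1L, 1L, 2L), 1L, prob = c(0.5, 0.25, 0.25))
      if (target_gap < 0L) {
        sep <- (r1 + r2) * stats::runif(1, 0.85, 1.0)
      } else {
        u <- c(sin(phi), cos(phi))
        sep <- shape_support(s1, u) + shape_support(s2, -u) + target_gap + 1
      }
      cy2 <- round(cy1 + sep * sin(phi)); cx2 <- round(cx1 + sep * cos(phi))
      if (cy2 < 0.4 * r2 || cy2 > h - 0.4 * r2 ||
          cx2 < 0.4 * r2 || cx2 > w - 0.4 * r2) next
      # the partner must clear every cell except its mate
      d <- if (nrow(centers)) sqrt((centers[, 1] - cy2)^2 + (centers[, 2] - cx2)^2) else numeric(0)
      if (length(d) && any(d < radii + s2$rmax + spec$min_gap_px)) next
      if (target_gap >= 0L) {
        # nudge until the measured silhouette gap matches the target
        adj <- adjust_pair_gap(s1, c(cy1, cx1), s2, c(cy2, cx2), target_gap, phi)
        if (is.null(adj)) next
        cy2 <- adj[1]; cx2 <- adj[2]
      }
      place(cy1, cx1, s1, next_id)
      place(cy2, cx2, s2, next_id + 1L)
      if (target_gap >= 0L)
        bridge_pairs[[length(bridge_pairs) + 1L]] <<- c(next_id, next_id + 1L)
      centers <<- rbind(centers, c(cy1, cx1), c(cy2, cx2))
      radii <<- c(radii, s1$rmax, s2$rmax)
      next_id <<- next_id + 2L
      return(TRUE)
    }
    FALSE
  }

  for (i in seq_len(n_pairs))
    if (!try_place_group(2L, TRUE))
      stop("generate_tile: could not place all cells; lower n_cells or radii")
  for (i in seq_len(n_single))
    if (!try_place_group(1L, FALSE))
      stop("generate_tile: could not place all cells; lower n_cells or radii")

  truth <- label_mask(lab)
  # the annotation gap between thin-gap pairs is not optically visible: the
  # stain runs continuously across adjacent cells, only the ground truth
  # separates them (the blurry-adjacency situation the corridor penalty and
  # the embedding strategy exist for)
  bridges <- lapply(bridge_pairs, function(ids) {
    a <- lab == ids[1]; b <- lab == ids[2]
    which(dilate8(dilate8(a)) & dilate8(dilate8(b)) & lab == 0L)
  })
  img <- render_tile(truth, spec, bridges = bridges)
  list(image = img, truth = truth)
}

# Paint an RGB image for a given instance mask under the spec's stain model.
# `bridges` lists pixel index sets to stain in foreground tone even though
# they are background in the mask (unannotated corridors between adjacent
# cells).
render_tile <- function(truth, spec, bridges = list()) {
  h <- nrow(truth); w <- ncol(truth)
  img <- array(0, c(h, w, 3))
  bg <- spec$stain_background
  # smooth background tone variation
  fy <- stats::runif(2, 0.5, 2); fx <- stats::runif(2, 0.5, 2); ph <- stats::runif(4, 0, 2 * pi)
  gy <- seq_len(h) / h; gx <- seq_len(w) / w
  field <- 0.02 * (outer(sin(2 * pi * fy[1] * gy + ph[1]), cos(2 * pi * fx[1] * gx + ph[2])) +
                   outer(cos(2 * pi * fy[2] * gy + ph[3]), sin(2 * pi * fx[2] * gx + ph[4])))
  for (c in 1:3) img[, , c] <- bg[c] + field
  # nucleus-like darker blue blobs in the background
  n_nuc <- max(0L, round(h * w / 2500))
  nuc_col <- bg * 0.55 + c(0.02, 0.02, 0.12)
  for (i in seq_len(n_nuc)) {
    cy <- stats::runif(1, 1, h); cx <- stats::runif(1, 1, w)
    ry <- stats::runif(1, 2.5, 5); rx <- stats::runif(1, 2.5, 5)
    ys <- max(1, floor(cy - ry)):min(h, ceiling(cy + ry))
    xs <- max(1, floor(cx - rx)):min(w, ceiling(cx + rx))
    d <- outer(((ys - cy) / ry)^2, ((xs - cx) / rx)^2, `+`)
    inside <- d <= 1
    for (c in 1:3) {
      sl <- img[ys, xs, c]
      sl[inside & truth[ys, xs] == 0L] <- nuc_col[c]
      img[ys, xs, c] <- sl
    }
  }
  # foreground stain with per-cell tone jitter and foamy inclusions
  m <- n_instances(truth)
  fgcol <- spec$stain_foreground
  for (k in seq_len(m)) {
    pix <- which(truth == k, arr.ind = TRUE)
    tone <- fgcol * stats::runif(1, 0.85, 1.15)
    tex <- stats::runif(nrow(pix), 0.93, 1.07)
    for (c in 1:3) {
      sl <- img[, , c]
      sl[pix] <- pmin(1, tone[c] * tex)
      img[, , c] <- sl
    }
    if (nrow(pix) > 600) {  # foamy cytoplasm in large cells
      n_holes <- sample(2:4, 1)
      idx <- pix[sample(nrow(pix), n_holes), , drop = FALSE]
      for (j in seq_len(n_holes)) {
        rr <- stats::runif(1, 1.5, 3.5)
        ys <- max(1, floor(idx[j, 1] - rr)):min(h, ceiling(idx[j, 1] + rr))
        xs <- max(1, floor(idx[j, 2] - rr)):min(w, ceiling(idx[j, 2] + rr))
        d <- outer((ys - idx[j, 1])^2, (xs - idx[j, 2])^2, `+`)
        inside <- d <= rr^2 & truth[ys, xs] == k
        for (c in 1:3) {
          sl <- img[ys, xs, c]
          sl[inside] <- pmin(1, sl[inside] * 1.5 + 0.15)
          img[ys, xs, c] <- sl
        }
      }
    }
  }
  for (br in bridges) {
    if (!length(br)) next
    tone <- fgcol * stats::runif(1, 0.9, 1.1)
    for (c in 1:3) {
      sl <- img[, , c]
      sl[br] <- pmin(1, tone[c] * stats::runif(length(br), 0.95, 1.05))
      img[, , c] <- sl
    }
  }
  if (spec$edge_blur_sigma > 0)
    img <- EBImage::imageData(EBImage::gblur(EBImage::Image(img, colormode = "Color"),
                                             sigma = spec$edge_blur_sigma))
  if (spec$noise_sigma > 0)
    img <- img + array(stats::rnorm(length(img), 0, spec$noise_sigma), dim(img))
  array(pmin(1, pmax(0, img)), c(h, w, 3))
}

#' Generate a patient-structured synthetic dataset
#'
#' Emulates a cohort in which each patient contributes `tiles_per_patient`
#' tiles. Per-patient jitter of cell density and stain tone induces
#' patient-level correlation, which is what makes patient-level splitting
#' ([split_by_patient()]) meaningful.
#'
#' @param n_patients Number of patients (>= 3).
#' @param tiles_per_patient Tiles per patient (default 3).
#' @param spec A [synthetic_tile_spec()] template; per-tile seeds and
#'   per-patient jitter are derived from `seed`.
#' @param seed Master seed for the dataset.
#' @return List of samples: `list(image, truth, patient_id, id)`.
#' @export
generate_dataset <- function(n_patients, tiles_per_patient = 3L,
                             spec = synthetic_tile_spec(), seed = 1L) {
  if (n_patients < 3L) stop("generate_dataset: need at least 3 patients")
  samples <- vector("list", n_patients * tiles_per_patient)
  idx <- 1L
  for (p in seq_len(n_patients)) {
    pseed <- (seed * 2654435L + p * 40503L) %% 2147483629L
    set.seed(pseed)
    density <- stats::runif(1, 0.8, 1.2)
    tone <- stats::runif(3, -0.04, 0.04)
    for (t in seq_len(tiles_per_patient)) {
      tspec <- spec
      tspec$n_cells <- max(1L, round(spec$n_cells * density))
      tspec$stain_foreground <- pmin(1, pmax(0, spec$stain_foreground + tone))
      tspec$seed <- as.integer((pseed + t * 7919L) %% 2147483629L)
      tile <- generate_tile(tspec)
      samples[[idx]] <- list(image = tile$image, truth = tile$truth,
                             patient_id = sprintf("patient_%03d", p),
                             id = sprintf("patient_%03d_tile_%d", p, t))
      idx <- idx + 1L
    }
  }
  samples
}

#' Fixture: two cells at an exact boundary gap
#'
#' Builds a tile containing exactly two disc-shaped cells whose silhouettes
#' are separated by exactly `gap_px` background pixels along their closest
#' approach (0 = touching: the binarized foreground is one connected
#' component while the truth has two instances — the semantic-vs-instance
#' distinction by construction).
#'
#' @param gap_px Exact background gap in pixels (>= 0).
#' @param seed Seed for the rendering randomness (geometry is deterministic).
#' @param radius Disc radius in pixels (default 14).
#' @return `list(image, truth)` with exactly two instances.
#' @export
make_touching_fixture <- function(gap_px = 0L, seed = 1L, radius = 14L) {
  stopifnot(gap_px >= 0, radius >= 3)
  set.seed(seed)
  r <- as.integer(radius)
  margin <- 10L
  cy <- r + margin
  cx1 <- r + margin
  cx2 <- cx1 + 2L * r + as.integer(gap_px) + 1L
  h <- 2L * (r + margin)
  w <- cx2 + r + margin
  lab <- matrix(0L, h, w)
  yy <- matrix(rep(seq_len(h), w), h, w)
  xx <- matrix(rep(seq_len(w), each = h), h, w)
  lab[(yy - cy)^2 + (xx - cx1)^2 <= r^2] <- 1L
  lab[(yy - cy)^2 + (xx - cx2)^2 <= r^2] <- 2L
  truth <- label_mask(lab)
  spec <- synthetic_tile_spec(height = h, width = w, n_cells = 2L, seed = seed)
  img <- render_tile(truth, spec)
  list(image = img, truth = truth)
}
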