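# Independent brute-force oracles used to verify the fast implementations.
# These deliberately use the most literal formulation available (explicit
# loops over pixel sets) and never share code with the package internals.

# Best Dice by exhaustive double loop over instance pixel sets.
oracle_best_dice <- function(a, b) {
  ids_a <- setdiff(sort(unique(as.vector(a))), 0L)
  ids_b <- setdiff(sort(unique(as.vector(b))), 0L)
  if (!length(ids_a)) stop("oracle_best_dice: empty first mask")
  if (!length(ids_b)) return(0)
  vals <- numeric(length(ids_a))
  for (i in seq_along(ids_a)) {
    pa <- which(a == ids_a[i])
    best <- 0
    for (j in seq_along(ids_b)) {
      pb <- which(b == ids_b[j])
      d <- 2 * length(intersect(pa, pb)) / (length(pa) + length(pb))
      if (d > best) best <- d
    }
    vals[i] <- best
  }
  mean(vals)
}

oracle_sbd <- function(a, b) min(oracle_best_dice(a, b), oracle_best_dice(b, a))

oracle_iou <- function(p, t) {
  pp <- which(p != 0); tt <- which(t != 0)
  u <- length(union(pp, tt))
  if (u == 0) return(1)
  length(intersect(pp, tt)) / u
}

oracle_dice <- function(p, t) {
  pp <- which(p != 0); tt <- which(t != 0)
  tot <- length(pp) + length(tt)
  if (tot == 0) return(1)
  2 * length(intersect(pp, tt)) / tot
}

# Weight map by direct per-pixel distance evaluation against every instance.
oracle_weight_map <- function(truth, proximity_px = 10, gap_weight = 3,
                              edge_weight = 0.5, base_weight = 1) {
  h <- nrow(truth); w <- ncol(truth)
  ids <- setdiff(sort(unique(as.vector(truth))), 0L)
  coords <- lapply(ids, function(k) which(truth == k, arr.ind = TRUE))
  wm <- matrix(base_weight, h, w)
  for (y in seq_len(h)) for (x in seq_len(w)) {
    if (truth[y, x] > 0L) {
      # edge = any 8-neighbour is background or off-grid
      edge <- FALSE
      for (dy in -1:1) for (dx in -1:1) {
        if (dy == 0 && dx == 0) next
        yy <- y + dy; xx <- x + dx
        if (yy < 1 || yy > h || xx < 1 || xx > w || truth[yy, xx] == 0L) edge <- TRUE
      }
      if (edge) wm[y, x] <- base_weight * edge_weight
    } else if (length(ids) >= 2) {
      d <- vapply(coords, function(pc)
        sqrt(min((pc[, 1] - y)^2 + (pc[, 2] - x)^2)), numeric(1))
      d <- sort(d)
      if (d[1] < proximity_px && d[2] < proximity_px)
        wm[y, x] <- base_weight * gap_weight
    }
  }
  wm
}

# Discriminative loss by direct loops over pixels and instance pairs.
oracle_disc_loss <- function(emb, truth, delta_v = 0.5, delta_d = 1.5,
                             alpha = 1, beta = 1, gamma = 0.001) {
  ids <- setdiff(sort(unique(as.vector(truth))), 0L)
  M <- length(ids)
  d <- dim(emb)[3]
  mus <- matrix(0, M, d)
  l_var <- 0
  for (k in seq_len(M)) {
    px <- which(truth == ids[k], arr.ind = TRUE)
    ek <- t(apply(px, 1, function(rc) emb[rc[1], rc[2], ]))
    if (d == 1) ek <- matrix(ek, ncol = 1)
    mus[k, ] <- colMeans(ek)
    hs <- apply(ek, 1, function(e) max(0, sqrt(sum((e - mus[k, ])^2)) - delta_v)^2)
    l_var <- l_var + mean(hs)
  }
  l_var <- l_var / M
  l_dist <- 0
  if (M >= 2) {
    cnt <- 0
    for (j in seq_len(M - 1)) for (k in (j + 1):M) {
      l_dist <- l_dist + max(0, 2 * delta_d - sqrt(sum((mus[j, ] - mus[k, ])^2)))^2
      cnt <- cnt + 1
    }
    l_dist <- l_dist / cnt
  }
  l_reg <- mean(apply(mus, 1, function(m) sqrt(sum(m^2))))
  alpha * l_var + beta * l_dist + gamma * l_reg
}

# Random blobby label mask: k seed points grow discs of random radius; pixels
# within a disc take the nearest seed's id. May yield fewer than k instances.
random_label_mask <- function(h = 32, w = 32, k = 5) {
  sy <- runif(k, 1, h); sx <- runif(k, 1, w)
  rad <- runif(k, 2, 0.45 * min(h, w))
  lab <- matrix(0L, h, w)
  for (y in seq_len(h)) for (x in seq_len(w)) {
    d <- sqrt((sy - y)^2 + (sx - x)^2)
    inside <- which(d <= rad)
    if (length(inside)) lab[y, x] <- inside[which.min(d[inside])]
  }
  lab
}

# Small sample builder shared by augmentation/training tests; cell radii
# scale with the tile so placement stays feasible at any size.
tiny_sample <- function(seed = 1, size = 64, n_cells = 4) {
  spec <- synthetic_tile_spec(height = size, width = size, n_cells = n_cells,
                              cell_radius_range = c(max(3, 0.07 * size),
                                                    max(5, 0.13 * size)),
                              touching_pair_fraction = 0, min_gap_px = 4,
                              seed = seed)
  s <- generate_tile(spec)
  s$patient_id <- sprintf("p%02d", seed)
  s$id <- sprintf("tile%03d", seed)
  s
}
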