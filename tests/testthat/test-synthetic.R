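test_that("tile generation is deterministic and honours the requested layout", {
  spec <- synthetic_tile_spec(height = 96, width = 96, n_cells = 5,
                              cell_radius_range = c(6, 12),
                              touching_pair_fraction = 0, min_gap_px = 5,
                              seed = 21)
  a <- generate_tile(spec)
  b <- generate_tile(spec)
  expect_identical(a$image, b$image)
  expect_identical(unclass(a$truth), unclass(b$truth))
  expect_identical(n_instances(a$truth), 5L)
  expect_identical(dim(a$image), c(96L, 96L, 3L))
  # non-touching cells keep the configured silhouette gap: no two instances
  # may have pixels within min_gap_px of each other
  sets <- lapply(seq_len(5), function(k) which(a$truth == k, arr.ind = TRUE))
  for (i in 1:4) for (j in (i + 1):5) {
    dmin <- min(sqrt(outer(sets[[i]][, 1], sets[[j]][, 1], "-")^2 +
                     outer(sets[[i]][, 2], sets[[j]][, 2], "-")^2))
    expect_gte(dmin, 5)
  }
})

test_that("empty tiles and infeasible specs behave as documented", {
  spec0 <- synthetic_tile_spec(height = 64, width = 64, n_cells = 0, seed = 1)
  t0 <- generate_tile(spec0)
  expect_identical(n_instances(t0$truth), 0L)
  expect_true(all(t0$image >= 0 & t0$image <= 1))
  crowded <- synthetic_tile_spec(height = 64, width = 64, n_cells = 60,
                                 cell_radius_range = c(12, 20), seed = 1)
  expect_error(generate_tile(crowded), "lower n_cells")
})

test_that("foreground and background stains are separable", {
  spec <- synthetic_tile_spec(height = 96, width = 96, n_cells = 6,
                              cell_radius_range = c(6, 12), seed = 31)
  tile <- generate_tile(spec)
  fg <- unclass(tile$truth) > 0
  mfg <- sapply(1:3, function(c) mean(tile$image[, , c][fg]))
  mbg <- sapply(1:3, function(c) mean(tile$image[, , c][!fg]))
  expect_gt(sqrt(sum((mfg - mbg)^2)), 0.15)
  # DAB brown vs hematoxylin blue: foreground redder, background bluer
  expect_gt(mfg[1] - mfg[3], 0)
  expect_gt(mbg[3] - mbg[1], 0)
})

test_that("mask areas are exact by construction", {
  spec <- synthetic_tile_spec(height = 96, width = 96, n_cells = 4,
                              cell_radius_range = c(6, 12), seed = 41)
  tile <- generate_tile(spec)
  st <- instance_stats(tile$truth)
  expect_identical(sum(st$area_px), sum(unclass(tile$truth) > 0))
  expect_identical(nrow(st), n_instances(tile$truth))
})

test_that("patient-structured datasets share per-patient styling", {
  spec <- synthetic_tile_spec(height = 64, width = 64, n_cells = 4,
                              cell_radius_range = c(5, 9), seed = 1)
  ds <- generate_dataset(4, 3, spec, seed = 9)
  expect_length(ds, 12)
  pids <- vapply(ds, `[[`, character(1), "patient_id")
  expect_identical(length(unique(pids)), 4L)
  # different patients draw different layouts
  expect_false(identical(ds[[1]]$truth, ds[[4]]$truth))
  expect_error(generate_dataset(2, 3, spec), "at least 3")
})

test_that("touching fixture has the exact requested gap", {
  for (gap in c(0L, 2L, 5L)) {
    fx <- make_touching_fixture(gap, seed = 3)
    expect_identical(n_instances(fx$truth), 2L)
    s1 <- which(fx$truth == 1, arr.ind = TRUE)
    s2 <- which(fx$truth == 2, arr.ind = TRUE)
    dmin <- min(sqrt(outer(s1[, 1], s2[, 1], "-")^2 +
                     outer(s1[, 2], s2[, 2], "-")^2))
    # closest-approach background gap of g px = centre distance g + 1
    expect_equal(dmin, gap + 1)
  }
  # gap 0: one connected component but two instances
  fx0 <- make_touching_fixture(0, seed = 3)
  cc <- semantic_to_instances(matrix(as.numeric(fx0$truth > 0), nrow(fx0$truth)))
  expect_identical(n_instances(cc), 1L)
  expect_identical(n_instances(fx0$truth), 2L)
})

test_that("raising the touching fraction produces more adjacent pairs", {
  close_pairs <- function(frac, seed) {
    spec <- synthetic_tile_spec(height = 128, width = 128, n_cells = 8,
                                cell_radius_range = c(6, 11),
                                touching_pair_fraction = frac, min_gap_px = 5,
                                seed = seed)
    truth <- generate_tile(spec)$truth
    m <- n_instances(truth)
    sets <- lapply(seq_len(m), function(k) which(truth == k, arr.ind = TRUE))
    cnt <- 0
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      dmin <- min(sqrt(outer(sets[[i]][, 1], sets[[j]][, 1], "-")^2 +
                       outer(sets[[i]][, 2], sets[[j]][, 2], "-")^2))
      if (dmin <= 3) cnt <- cnt + 1
    }
    cnt
  }
  lo <- sum(vapply(1:5, function(s) close_pairs(0, s), numeric(1)))
  hi <- sum(vapply(1:5, function(s) close_pairs(0.5, s), numeric(1)))
  expect_lt(lo, hi)
  expect_identical(lo, 0)
})
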