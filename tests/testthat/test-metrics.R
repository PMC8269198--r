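test_that("iou and dice match hand-counted examples and conventions", {
  # P covers 6 pixels, T covers 4, overlap 3 -> union 7
  p <- matrix(FALSE, 4, 4); t <- matrix(FALSE, 4, 4)
  p[1:6] <- TRUE; t[4:7] <- TRUE
  expect_equal(iou(binary_mask(p), binary_mask(t)), 3 / 7)
  expect_equal(dice(binary_mask(p), binary_mask(t)), 2 * 3 / 10)

  ident <- binary_mask(matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2))
  expect_identical(iou(ident, ident), 1)
  expect_identical(dice(ident, ident), 1)

  disj_a <- binary_mask(matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
  disj_b <- binary_mask(matrix(c(FALSE, FALSE, FALSE, TRUE), 2, 2))
  expect_identical(iou(disj_a, disj_b), 0)

  empty <- binary_mask(matrix(FALSE, 2, 2))
  expect_identical(iou(empty, empty), 1)
  expect_identical(dice(empty, empty), 1)
  expect_identical(iou(empty, ident), 0)

  expect_error(iou(empty, binary_mask(matrix(FALSE, 3, 2))), "shape")
})

test_that("dice is the 2u/(1+u) transform of iou and never below it", {
  set.seed(101)
  for (i in 1:50) {
    a <- random_label_mask(24, 24, sample(1:8, 1)) > 0
    b <- random_label_mask(24, 24, sample(1:8, 1)) > 0
    u <- iou(binary_mask(a), binary_mask(b))
    d <- dice(binary_mask(a), binary_mask(b))
    expect_equal(d, 2 * u / (1 + u), tolerance = 1e-12)
    expect_gte(d, u)
    expect_true(u >= 0 && d <= 1)
  }
})

test_that("best_dice reproduces hand computations and is non-commutative", {
  # a: one 3-pixel instance; b: the same plus an extra 2-pixel instance
  a <- matrix(0L, 3, 3); a[1, 1:3] <- 1L
  b <- a; b[3, 1:2] <- 2L
  la <- label_mask(a); lb <- label_mask(b)
  expect_equal(best_dice(la, lb), 1.0)
  expect_equal(best_dice(lb, la), 0.5)
  expect_equal(sbd(la, lb), 0.5)
  expect_equal(sbd(lb, la), 0.5)

  # A1 (4 px), A2 (2 px); B1 (3 px inside A1), B2 (3 px, 2 shared with A2)
  a2 <- matrix(0L, 4, 4); b2 <- matrix(0L, 4, 4)
  a2[1, 1:4] <- 1L; a2[3, 1:2] <- 2L
  b2[1, 1:3] <- 1L; b2[3, 1:3] <- 2L
  BD <- best_dice(label_mask(a2), label_mask(b2))
  expect_equal(BD, (2 * 3 / (4 + 3) + 2 * 2 / (2 + 3)) / 2)  # (6/7 + 4/5)/2
  expect_equal(BD, 0.8285714, tolerance = 1e-6)
})

test_that("sbd edge conventions and self-identity hold", {
  empty <- label_mask(matrix(0L, 4, 4))
  one <- label_mask(matrix(c(1L, rep(0L, 15)), 4, 4))
  expect_identical(sbd(empty, empty), 1)
  expect_identical(sbd(one, empty), 0)
  expect_identical(sbd(empty, one), 0)
  expect_error(best_dice(empty, one), "zero instances")
  expect_identical(sbd(one, one), 1)
})

test_that("metrics agree with brute-force oracles on random label masks", {
  set.seed(202)
  for (i in 1:60) {
    a <- label_mask(random_label_mask(32, 32, sample(2:10, 1)))
    b <- label_mask(random_label_mask(32, 32, sample(2:10, 1)))
    if (n_instances(a) == 0 || n_instances(b) == 0) next
    expect_equal(best_dice(a, b), oracle_best_dice(a, b), tolerance = 1e-12)
    expect_equal(sbd(a, b), oracle_sbd(a, b), tolerance = 1e-12)
    expect_equal(sbd(a, b), sbd(b, a), tolerance = 1e-15)
    expect_equal(iou(binarize(a), binarize(b)), oracle_iou(a, b), tolerance = 1e-12)
  }
})

test_that("metrics are invariant under relabeling and joint translation", {
  set.seed(303)
  a <- label_mask(random_label_mask(28, 28, 6))
  b <- label_mask(random_label_mask(28, 28, 5))
  # relabel: permute ids of a
  perm <- sample(n_instances(a))
  ap <- matrix(0L, 28, 28)
  for (k in seq_len(n_instances(a))) ap[a == k] <- perm[k]
  expect_equal(sbd(label_mask(ap, canonical = FALSE), b), sbd(a, b), tolerance = 1e-12)
  expect_identical(sbd(a, relabel_canonical(a)), 1)
  # joint translation by (3, 2) on a larger canvas
  big <- function(m, dy, dx) {
    out <- matrix(0L, 40, 40); out[dy + 1:28, dx + 1:28] <- m; out
  }
  expect_equal(sbd(label_mask(big(a, 3, 2), canonical = FALSE),
                   label_mask(big(b, 3, 2), canonical = FALSE)),
               sbd(a, b), tolerance = 1e-12)
})

test_that("relabel_canonical compacts ids and preserves partitions", {
  m <- matrix(0L, 3, 3); m[1, 1] <- 7L; m[2, 2] <- 42L
  cm <- relabel_canonical(m)
  expect_setequal(unique(as.vector(cm)), c(0L, 1L, 2L))
  expect_identical(relabel_canonical(cm), cm)
  expect_error(relabel_canonical(matrix(-1L, 2, 2)), "negative")
  expect_error(label_mask(matrix(-3, 2, 2)), "negative")
})

test_that("evaluate_dataset aggregates to the percent scale with sample stdev", {
  m <- label_mask(random_label_mask(16, 16, 3))
  rep1 <- evaluate_dataset(list(list(predicted = m, truth = m)))
  expect_equal(rep1$iou_mean, 100)
  expect_equal(rep1$sbd_mean, 100)
  expect_equal(rep1$iou_stdev, 0)

  half <- matrix(0L, 4, 4); half[, 1:2] <- 1L
  full <- matrix(0L, 4, 4); full[, ] <- 1L
  pairs <- list(
    list(predicted = label_mask(full), truth = label_mask(full)),  # IoU 1
    list(predicted = label_mask(half), truth = label_mask(full)))  # IoU 0.5
  rep2 <- evaluate_dataset(pairs)
  expect_equal(rep2$iou_mean, 75)
  expect_equal(rep2$iou_stdev, 100 * stats::sd(c(1, 0.5)))
  expect_error(evaluate_dataset(list()), "empty")
})

test_that("metric reports round-trip through JSON and CSV writers", {
  set.seed(5)
  pairs <- lapply(1:3, function(i) {
    m <- label_mask(random_label_mask(16, 16, 3))
    n <- label_mask(random_label_mask(16, 16, 3))
    list(predicted = m, truth = n, id = paste0("img", i))
  })
  rep <- evaluate_dataset(pairs, model = "deeplabv3", strategy = "instance")
  jpath <- tempfile(fileext = ".json")
  write_metric_report_json(rep, jpath)
  back <- read_metric_report_json(jpath)
  expect_equal(back$iou_mean, rep$iou_mean)
  expect_equal(back$sbd_stdev, rep$sbd_stdev)
  expect_equal(back$per_image$iou, rep$per_image$iou)

  cpath <- tempfile(fileext = ".csv")
  write_metric_report_csv(rep, cpath)
  csv <- read.csv(cpath)
  expect_identical(names(csv),
                   c("model", "strategy", "iou_mean", "iou_stdev", "sbd_mean", "sbd_stdev"))
  expect_equal(csv$iou_mean, round(rep$iou_mean, 4))
})

test_that("mask images survive the 16-bit round trip", {
  set.seed(6)
  m <- label_mask(random_label_mask(20, 24, 6))
  p <- tempfile(fileext = ".tif")
  write_label_mask(m, p)
  back <- read_label_mask(p)
  expect_identical(unclass(back), unclass(m))

  bm <- binarize(m)
  pb <- tempfile(fileext = ".png")
  write_binary_mask(bm, pb)
  expect_identical(unclass(read_binary_mask(pb)), unclass(bm))
})
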