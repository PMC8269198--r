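test_that("discriminative loss limits match closed forms", {
  par <- disc_loss_params(gamma = 0)
  # two instances embedded at constant vectors 10*delta_d apart: both hinges off
  truth <- label_mask(matrix(c(rep(1L, 8), rep(2L, 8)), 4, 4), canonical = FALSE)
  emb <- array(0, c(4, 4, 2))
  emb[, 3:4, 1] <- 10 * par$delta_d
  expect_equal(discriminative_loss(emb, truth, par), 0)

  # fully collapsed centroids: each pair contributes (2*delta_d)^2
  emb0 <- array(0, c(4, 4, 2))
  expect_equal(discriminative_loss(emb0, truth, par), (2 * par$delta_d)^2)
  three <- label_mask(matrix(c(rep(1L, 4), rep(2L, 4), rep(3L, 8)), 4, 4),
                      canonical = FALSE)
  expect_equal(discriminative_loss(array(0, c(4, 4, 3)), three, par),
               (2 * par$delta_d)^2)

  # pixels exactly at distance delta_v from the centroid: variance hinge at 0
  one <- label_mask(matrix(1L, 2, 2), canonical = FALSE)
  embv <- array(0, c(2, 2, 1))
  embv[, , 1] <- c(-par$delta_v, par$delta_v, -par$delta_v, par$delta_v)
  expect_equal(discriminative_loss(embv, one, par), 0)
  expect_error(discriminative_loss(emb, label_mask(matrix(0L, 4, 4))), "zero instances")
})

test_that("discriminative loss agrees with the brute-force oracle", {
  set.seed(71)
  for (i in 1:8) {
    h <- sample(6:14, 1); w <- sample(6:14, 1)  # <= 196 pixels
    truth <- label_mask(random_label_mask(h, w, sample(2:5, 1)))
    if (n_instances(truth) == 0) next
    emb <- array(rnorm(h * w * 3), c(h, w, 3))
    expect_equal(discriminative_loss(emb, truth),
                 oracle_disc_loss(emb, truth), tolerance = 1e-6)
  }
})

test_that("discriminative loss is invariant under relabeling and pixel order", {
  set.seed(72)
  truth <- label_mask(random_label_mask(10, 10, 4))
  emb <- array(rnorm(300), c(10, 10, 3))
  l0 <- discriminative_loss(emb, truth)
  perm <- sample(n_instances(truth))
  shuf <- matrix(0L, 10, 10)
  for (k in seq_len(n_instances(truth))) shuf[truth == k] <- perm[k]
  expect_equal(discriminative_loss(emb, label_mask(shuf, canonical = FALSE)), l0,
               tolerance = 1e-12)
})

test_that("discriminative loss gradient matches finite differences", {
  set.seed(73)
  truth <- label_mask(random_label_mask(8, 8, 3))
  emb <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  par <- disc_loss_params()
  g <- tamseg:::disc_loss_grad(emb, truth, par)$grad
  for (j in sample(length(emb), 8)) {
    eps <- 1e-6
    ep <- emb; ep[j] <- ep[j] + eps
    em <- emb; em[j] <- em[j] - eps
    fd <- (discriminative_loss(ep, truth, par) -
           discriminative_loss(em, truth, par)) / (2 * eps)
    expect_equal(g[j], fd, tolerance = 1e-4)
  }
})

test_that("assemble_loss composes strategies correctly", {
  set.seed(74)
  h <- 8; w <- 8
  truth <- label_mask(random_label_mask(h, w, 2))
  out <- list(class_scores = array(rnorm(h * w * 2), c(h, w, 2)),
              embeddings = array(rnorm(h * w * 4), c(h, w, 4)))
  vanilla <- assemble_loss("vanilla", out, truth)
  unit_wm <- matrix(1, h, w)
  expect_equal(assemble_loss("weighted", out, truth, weight_map = unit_wm),
               vanilla, tolerance = 1e-12)
  inst <- assemble_loss("instance", out, truth)
  expect_gte(inst, vanilla)
  expect_error(assemble_loss("weighted", out, truth), "weight_map")
  expect_error(assemble_loss("instance", list(class_scores = out$class_scores),
                             truth), "embeddings")
  # perfect prediction -> zero CE
  perfect <- array(0, c(h, w, 2))
  perfect[, , 2][unclass(truth) > 0] <- 60
  perfect[, , 1][unclass(truth) == 0] <- 60
  expect_lt(assemble_loss("vanilla", list(class_scores = perfect), truth), 1e-12)
})

test_that("plateau schedule halves the lr exactly on schedule", {
  st <- lr_schedule_step(NULL, NULL, lr = 1e-4)
  st <- lr_schedule_step(st, 1.0)  # first observation improves on Inf
  for (i in 1:14) st <- lr_schedule_step(st, 1.0)
  expect_equal(st$lr, 1e-4)       # 14 stalls: unchanged
  st <- lr_schedule_step(st, 1.0) # 15th consecutive stall
  expect_equal(st$lr, 5e-5)
  # improvement resets the counter
  st2 <- lr_schedule_step(NULL, NULL, lr = 1e-4)
  st2 <- lr_schedule_step(st2, 1.0)
  for (i in 1:14) st2 <- lr_schedule_step(st2, 1.0)
  st2 <- lr_schedule_step(st2, 0.5)
  for (i in 1:14) st2 <- lr_schedule_step(st2, 0.5)
  expect_equal(st2$lr, 1e-4)
  # three consecutive plateaus: 1e-4 / 2^3
  st3 <- lr_schedule_step(NULL, NULL, lr = 1e-4)
  st3 <- lr_schedule_step(st3, 1.0)
  for (i in 1:45) st3 <- lr_schedule_step(st3, 1.0)
  expect_equal(st3$lr, 1.25e-5)
})

test_that("training is deterministic, reduces the loss and logs the schedule", {
  set.seed(75)
  samples <- lapply(1:8, function(i) tiny_sample(seed = i, size = 32, n_cells = 2))
  run <- function() {
    set.seed(99)
    model <- build_model(model_config("deeplabv3", base_channels = 4))
    tc <- train_config("vanilla", batch_size = 2, max_iters = 60,
                       patch_size = 32, val_every = 20, seed = 99)
    train(model, samples[1:6], samples[7:8], tc)
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$log$train_loss, f2$log$train_loss)
  expect_true(all(diff(f1$log$lr) <= 0))
  first <- mean(head(f1$log$train_loss, 10))
  last <- mean(tail(f1$log$train_loss, 10))
  expect_lt(last, first)
  expect_identical(names(f1$log), c("iter", "train_loss", "val_loss", "lr"))
})
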