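test_that("all families produce full-resolution outputs of the right shape", {
  set.seed(61)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  for (fam in c("unet", "segnet", "deeplabv3")) {
    m <- build_model(model_config(fam, base_channels = 4))
    out <- model_forward(m, x)
    expect_identical(dim(out$class_scores), c(32L, 32L, 2L))
    expect_null(out$embeddings)
  }
  mb <- build_model(model_config("deeplabv3", base_channels = 4,
                                 backbone = "mobilenetv2_style"))
  expect_identical(dim(model_forward(mb, x)$class_scores), c(32L, 32L, 2L))
})

test_that("tiny variants stay under 1e5 parameters and widths scale", {
  for (fam in c("unet", "segnet", "deeplabv3")) {
    tiny <- build_model(model_config(fam, base_channels = 4))
    expect_lt(tamseg:::nn_param_count(tiny$net), 1e5)
    wide <- build_model(model_config(fam, base_channels = 8))
    expect_gt(tamseg:::nn_param_count(wide$net),
              2 * tamseg:::nn_param_count(tiny$net))
  }
})

test_that("identical seeds give identical initial weights and outputs", {
  cfg <- model_config("deeplabv3", base_channels = 4, embedding_dim = 4)
  set.seed(62); m1 <- build_model(cfg)
  set.seed(62); m2 <- build_model(cfg)
  expect_identical(tamseg:::nn_get_weights(m1$net), tamseg:::nn_get_weights(m2$net))
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_identical(model_forward(m1, x), model_forward(m2, x))
})

test_that("embedding decoder adds an independent branch with its own gradients", {
  set.seed(63)
  model <- build_model(model_config("deeplabv3", base_channels = 4, use_coords = FALSE))
  sem_params_before <- lapply(tamseg:::nn_ancestor_params(model$net, model$nodes$semantic),
                              function(p) list(w = p$w, b = p$b))
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  out_before <- model_forward(model, x)$class_scores
  model <- add_embedding_decoder(model, 5L)
  out <- model_forward(model, x)
  expect_identical(dim(out$embeddings), c(16L, 16L, 5L))
  # the semantic head's output is unchanged by attaching the branch
  expect_identical(out$class_scores, out_before)
  expect_error(add_embedding_decoder(model, 1L), ">= 2")

  # discriminative-loss gradients vanish on semantic-decoder-exclusive params
  truth <- label_mask(matrix(rep(c(0L, 1L, 2L, 0L), each = 64), 16, 16),
                      canonical = FALSE)
  fwd <- tamseg:::model_forward_full(model, x)
  emb <- array(fwd$vals[[model$nodes$embedding]], c(16, 16, 5))
  g <- tamseg:::disc_loss_grad(emb, truth, disc_loss_params())$grad
  grads <- stats::setNames(list(array(g, c(16, 16, 5, 1))),
                           as.character(model$nodes$embedding))
  tamseg:::nn_backward(model$net, fwd, grads)
  emb_params <- tamseg:::nn_ancestor_params(model$net, model$nodes$embedding)
  sem_params <- tamseg:::nn_ancestor_params(model$net, model$nodes$semantic)
  sem_only <- setdiff(sapply(sem_params, rlang::obj_address),
                      sapply(emb_params, rlang::obj_address))
  for (p in sem_params)
    if (rlang::obj_address(p) %in% sem_only) expect_null(p$gw)
  # but some embedding-branch parameter did receive gradient
  expect_true(any(vapply(emb_params, function(p) !is.null(p$gw) && any(p$gw != 0),
                         logical(1))))
})

test_that("networks are translation-covariant on interior pixels", {
  set.seed(64)
  m <- build_model(model_config("deeplabv3", base_channels = 4, use_coords = FALSE))
  base <- array(runif(48 * 48 * 3), c(48, 48, 3))
  shift <- 4  # one full network stride
  big <- array(runif(56 * 56 * 3), c(56, 56, 3))
  big[1:48, 1:48, ] <- base
  a <- model_forward(m, big[1:48, 1:48, , drop = FALSE])$class_scores
  shifted <- big[(1 + shift):(48 + shift), (1 + shift):(48 + shift), , drop = FALSE]
  # place the same content shifted by `shift`: compare interior windows
  big2 <- array(runif(56 * 56 * 3), c(56, 56, 3))
  big2[(1 + shift):(48 + shift), (1 + shift):(48 + shift), ] <- base
  b <- model_forward(m, big2[(1 + shift):(48 + shift), (1 + shift):(48 + shift), ,
                             drop = FALSE])$class_scores
  interior <- 13:36
  expect_equal(a[interior, interior, ], b[interior, interior, ], tolerance = 1e-8)
})

test_that("checkpoints round-trip weights and config manifest", {
  set.seed(65)
  model <- build_model(model_config("unet", base_channels = 4, embedding_dim = 3))
  path <- tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_identical(back$config$family, "unet")
  expect_identical(back$config$embedding_dim, 3L)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_identical(model_forward(back, x), model_forward(model, x))
})

test_that("invalid configurations are rejected", {
  expect_error(model_config("unet", base_channels = 2), ">= 4")
  expect_error(model_config("unet", embedding_dim = 1), ">= 2")
  expect_error(build_model(structure(list(family = "resnet"), class = "model_config")))
  m <- build_model(model_config("unet", base_channels = 4))
  expect_error(model_forward(m, array(0, c(30, 30, 3))), "divisible")
})
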