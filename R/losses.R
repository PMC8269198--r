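#' Discriminative (pull/push) loss parameters
#'
#' The pixel-embedding instance loss has three terms: a hinged
#' within-instance variance term that pulls each instance's pixel embeddings
#' to within `delta_v` of their centroid, a hinged between-centroid term that
#' pushes centroids of different instances at least `2 * delta_d` apart, and
#' a small centroid-norm regularizer. Cluster separability at prediction
#' time is guaranteed when `delta_d > 2 * delta_v`.
#'
#' @param delta_v Pull (variance) margin, default 0.5.
#' @param delta_d Push (distance) margin, default 1.5.
#' @param alpha,beta,gamma Term weights for variance, distance and
#'   regularization (defaults 1, 1, 0.001).
#' @return A `disc_loss_params` list.
#' @export
disc_loss_params <- function(delta_v = 0.5, delta_d = 1.5,
                             alpha = 1, beta = 1, gamma = 0.001) {
  stopifnot(delta_v > 0, delta_d > 0, alpha >= 0, beta >= 0, gamma >= 0)
  structure(list(delta_v = delta_v, delta_d = delta_d,
                 alpha = alpha, beta = beta, gamma = gamma),
            class = "disc_loss_params")
}

#' Discriminative loss on a pixel-embedding field
#'
#' `alpha * mean_k mean_{p in k} max(0, ||e_p - mu_k|| - delta_v)^2 +
#'  beta * mean_{j<k} max(0, 2 delta_d - ||mu_j - mu_k||)^2 +
#'  gamma * mean_k ||mu_k||`,
#' where `mu_k` is the centroid of instance `k`'s embeddings. The loss is
#' zero (with `gamma = 0`) exactly when every instance's pixels lie within
#' `delta_v` of their centroid and all centroid pairs are at least
#' `2 * delta_d` apart. With a single instance the distance term is defined
#' as 0. Invariant under instance relabeling and pixel order.
#'
#' @param embeddings `H x W x n` numeric array (the embedding field).
#' @param truth A [label_mask()] with at least one instance.
#' @param params A [disc_loss_params()].
#' @return Non-negative scalar.
#' @export
discriminative_loss <- function(embeddings, truth, params = disc_loss_params()) {
  disc_loss_grad(embeddings, truth, params, want_grad = FALSE)$loss
}

# Loss and (optionally) gradient w.r.t. the embedding field.
disc_loss_grad <- function(embeddings, truth, params, want_grad = TRUE) {
  d <- dim(embeddings)
  if (!identical(d[1:2], dim(truth)))
    stop("discriminative_loss: embedding/truth shape mismatch")
  sets <- instance_pixel_sets(truth)
  M <- length(sets)
  if (M == 0L) stop("discriminative_loss: truth has zero instances")
  ndim <- d[3]
  npix <- d[1] * d[2]
  E <- matrix(embeddings, npix, ndim)  # rows = pixels
  grad <- if (want_grad) matrix(0, npix, ndim) else NULL

  mus <- matrix(0, M, ndim)
  l_var <- 0
  for (k in seq_len(M)) {
    idx <- sets[[k]]
    Ek <- E[idx, , drop = FALSE]
    mu <- colMeans(Ek)
    mus[k, ] <- mu
    r <- sweep(Ek, 2, mu)
    nrm <- sqrt(rowSums(r^2))
    hinge <- pmax(0, nrm - params$delta_v)
    l_var <- l_var + mean(hinge^2)
    if (want_grad && any(hinge > 0)) {
      # d/d e_p of (1/(M N_k)) sum h^2, including the path through mu_k
      act <- hinge > 0
      coef <- ifelse(act, 2 * hinge / pmax(nrm, 1e-12), 0)
      gk <- r * coef / (M * length(idx))
      gk <- sweep(gk, 2, colMeans(gk))  # centroid path subtracts the mean
      grad[idx, ] <- grad[idx, ] + params$alpha * gk
    }
  }
  l_var <- l_var / M

  l_dist <- 0
  if (M >= 2L) {
    npairs <- M * (M - 1) / 2
    dmu <- if (want_grad) matrix(0, M, ndim) else NULL
    for (j in seq_len(M - 1L)) {
      for (k in (j + 1L):M) {
        diff <- mus[j, ] - mus[k, ]
        dist <- sqrt(sum(diff^2))
        h <- 2 * params$delta_d - dist
        if (h > 0) {
          l_dist <- l_dist + h^2
          if (want_grad) {
            g <- -2 * h * (if (dist > 1e-12) diff / dist else rep(0, ndim)) / npairs
            dmu[j, ] <- dmu[j, ] + g
            dmu[k, ] <- dmu[k, ] - g
          }
        }
      }
    }
    l_dist <- l_dist / npairs
    if (want_grad) {
      for (k in seq_len(M)) {
        idx <- sets[[k]]
        grad[idx, ] <- grad[idx, ] +
          params$beta * matrix(dmu[k, ], length(idx), ndim, byrow = TRUE) / length(idx)
      }
    }
  }

  mu_norm <- sqrt(rowSums(mus^2))
  l_reg <- mean(mu_norm)
  if (want_grad && params$gamma > 0) {
    for (k in seq_len(M)) {
      if (mu_norm[k] > 1e-12) {
        idx <- sets[[k]]
        grad[idx, ] <- grad[idx, ] + params$gamma *
          matrix(mus[k, ] / mu_norm[k], length(idx), ndim, byrow = TRUE) / (M * length(idx))
      }
    }
  }

  loss <- params$alpha * l_var + params$beta * l_dist + params$gamma * l_reg
  list(loss = loss,
       grad = if (want_grad) array(grad, d) else NULL,
       centroids = mus)
}

# Softmax cross-entropy (optionally pixel-weighted) with gradient w.r.t.
# logits. z: (H, W, 2) logits, channel 2 = foreground.
ce_loss_grad <- function(z, truth, weights = NULL, want_grad = TRUE) {
  t <- as_fg(truth)
  h <- dim(z)[1]; w <- dim(z)[2]
  if (is.null(weights)) weights <- matrix(1, h, w) else weights <- unclass(weights)
  m <- pmax(z[, , 1], z[, , 2])
  e0 <- exp(z[, , 1] - m); e1 <- exp(z[, , 2] - m)
  s <- e0 + e1
  p1 <- e1 / s
  eps <- 1e-12
  ce <- -(t * log(pmax(p1, eps)) + (1 - t) * log(pmax(1 - p1, eps)))
  loss <- mean(weights * ce)
  grad <- NULL
  if (want_grad) {
    npix <- h * w
    grad <- array(0, c(h, w, 2))
    grad[, , 2] <- weights * (p1 - t) / npix
    grad[, , 1] <- -grad[, , 2]
  }
  list(loss = loss, grad = grad)
}

#' Assemble the strategy loss for one sample
#'
#' `vanilla` = pixel cross-entropy; `weighted` = weight-map-scaled pixel
#' cross-entropy; `instance` = cross-entropy plus the discriminative loss on
#' the embedding field (unit weights between the two terms). The instance
#' loss is therefore never below its cross-entropy component.
#'
#' @param strategy `"vanilla"`, `"weighted"` or `"instance"`.
#' @param network_output `list(class_scores, embeddings)` as returned by
#'   [model_forward()].
#' @param truth A [label_mask()].
#' @param weight_map Required for `"weighted"`.
#' @param params [disc_loss_params()] for `"instance"`.
#' @return Scalar loss.
#' @export
assemble_loss <- function(strategy = c("vanilla", "weighted", "instance"),
                          network_output, truth, weight_map = NULL,
                          params = disc_loss_params()) {
  strategy <- match.arg(strategy)
  if (strategy == "weighted" && is.null(weight_map))
    stop("assemble_loss: strategy 'weighted' requires a weight_map")
  if (strategy == "instance" && is.null(network_output$embeddings))
    stop("assemble_loss: strategy 'instance' requires network embeddings")
  ce <- ce_loss_grad(network_output$class_scores, truth,
                     weights = if (strategy == "weighted") weight_map else NULL,
                     want_grad = FALSE)$loss
  if (strategy == "instance")
    ce <- ce + discriminative_loss(network_output$embeddings, truth, params)
  ce
}

#' Plateau learning-rate schedule
#'
#' Tracks the best observed loss; when the loss fails to improve (by more
#' than a relative tolerance `eps`) for `patience` consecutive optimizer
#' steps, the learning rate is multiplied by `factor` and the stall counter
#' resets. Any improvement also resets the counter. The produced lr sequence
#' is non-increasing.
#'
#' @param state `NULL` to initialize, or the state returned by a previous
#'   call. Initialization parameters: `lr` (1e-4), `factor` (0.5),
#'   `patience` (15), `eps` (1e-4), `min_lr` (0).
#' @param current_loss The loss of the step just taken.
#' @param lr,factor,patience,eps,min_lr Initialization parameters (used when
#'   `state` is `NULL`); `min_lr` floors the decay (0 = no floor).
#' @return The updated state list (`$lr` holds the current learning rate).
#' @export
lr_schedule_step <- function(state = NULL, current_loss = NULL, lr = 1e-4,
                             factor = 0.5, patience = 15L, eps = 1e-4,
                             min_lr = 0) {
  if (is.null(state))
    state <- list(lr = lr, factor = factor, patience = as.integer(patience),
                  eps = eps, min_lr = min_lr, best = Inf, stall = 0L)
  if (is.null(current_loss)) return(state)
  if (current_loss < state$best * (1 - state$eps)) {
    state$best <- current_loss
    state$stall <- 0L
  } else {
    state$stall <- state$stall + 1L
    if (state$stall >= state$patience) {
      state$lr <- max(state$lr * state$factor, state$min_lr %||% 0)
      state$stall <- 0L
    }
  }
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Training configuration
#'
#' @param strategy `"vanilla"`, `"weighted"` or `"instance"`.
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param lr_decay_factor Plateau decay factor (default 0.5).
#' @param min_lr Floor for the decayed learning rate (default 0, i.e. pure
#'   halving; desk-scale runs benefit from a small positive floor so a noisy
#'   plateau cannot freeze training).
#' @param plateau_patience Consecutive non-improving optimizer steps before
#'   decay (default 15).
#' @param improve_eps Relative improvement tolerance for the plateau
#'   detector (default 1e-4).
#' @param batch_size Samples per optimizer step (default 8).
#' @param max_iters Optimizer step budget.
#' @param patch_size Training patch side (default 224; tiles equal to the
#'   patch are used whole).
#' @param val_every Validation cadence in optimizer steps (default 25).
#' @param early_stop_margin,early_stop_patience Stop when the validation
#'   loss exceeds its running best by `margin` (relative, default 5%) for
#'   `patience` consecutive validation checks (default 10) — the
#'   "validation diverges from training" rule.
#' @param disc_params [disc_loss_params()] for the instance strategy.
#' @param disc_weight Weight of the discriminative term relative to the
#'   cross-entropy (default 1: unit weights between the two terms). Small
#'   unnormalized networks train more stably with this reduced (the
#'   discriminative gradients on the shared encoder are much larger than the
#'   cross-entropy gradients); see the methods vignette.
#' @param augment An [augmentation_config()] or `NULL` to disable.
#' @param weight_map_args Arguments passed to [compute_weight_map()] for the
#'   weighted strategy.
#' @param seed Master seed for all training randomness.
#' @return A `train_config` list.
#' @export
train_config <- function(strategy = c("vanilla", "weighted", "instance"),
                         learning_rate = 1e-4, lr_decay_factor = 0.5,
                         min_lr = 0,
                         plateau_patience = 15L, improve_eps = 1e-4,
                         batch_size = 8L, max_iters = 300L, patch_size = 224L,
                         val_every = 25L, early_stop_margin = 0.05,
                         early_stop_patience = 10L,
                         disc_params = disc_loss_params(), disc_weight = 1,
                         augment = NULL,
                         weight_map_args = list(), seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(learning_rate > 0, plateau_patience >= 1, batch_size >= 1,
            max_iters >= 1, disc_weight >= 0)
  structure(list(strategy = strategy, learning_rate = learning_rate,
                 lr_decay_factor = lr_decay_factor, min_lr = min_lr,
                 plateau_patience = as.integer(plateau_patience),
                 improve_eps = improve_eps, batch_size = as.integer(batch_size),
                 max_iters = as.integer(max_iters),
                 patch_size = as.integer(patch_size),
                 val_every = as.integer(val_every),
                 early_stop_margin = early_stop_margin,
                 early_stop_patience = as.integer(early_stop_patience),
                 disc_params = disc_params, disc_weight = disc_weight,
                 augment = augment,
                 weight_map_args = weight_map_args, seed = as.integer(seed)),
            class = "train_config")
}

# Loss and output-node gradients for one prepared sample.
sample_loss_grads <- function(model, fwd, sample, config) {
  cs <- fwd$vals[[model$nodes$semantic]]
  cs3 <- array(cs, dim(cs)[1:3])
  wm <- if (config$strategy == "weighted") sample$weight_map else NULL
  ce <- ce_loss_grad(cs3, sample$truth, weights = wm)
  grads <- list()
  grads[[as.character(model$nodes$semantic)]] <- array(ce$grad, c(dim(cs3), 1L))
  loss <- ce$loss
  if (config$strategy == "instance") {
    emb <- fwd$vals[[model$nodes$embedding]]
    emb3 <- array(emb, dim(emb)[1:3])
    dw <- if (is.null(config$disc_weight)) 1 else config$disc_weight
    if (n_instances(sample$truth) >= 1L && dw > 0) {
      dl <- disc_loss_grad(emb3, sample$truth, config$disc_params)
      loss <- loss + dw * dl$loss
      grads[[as.character(model$nodes$embedding)]] <- array(dw * dl$grad, c(dim(emb3), 1L))
    }
  }
  list(loss = loss, grads = grads)
}

prepare_sample <- function(sample, config) {
  if (config$strategy == "weighted" && is.null(sample$weight_map))
    sample$weight_map <- do.call(compute_weight_map,
                                 c(list(sample$truth), config$weight_map_args))
  if (!is.null(config$augment)) sample <- augment(sample, config$augment)
  if (dim(sample$image)[1] > config$patch_size ||
      dim(sample$image)[2] > config$patch_size)
    sample <- sample_patch(sample, config$patch_size)
  sample
}

#' Train a segmentation model
#'
#' Iterates randomly drawn (optionally augmented) patches, takes Adam steps
#' on the assembled strategy loss, decays the learning rate on training-loss
#' plateaus (the plateau detector watches an exponentially smoothed loss,
#' smoothing factor 0.1, since raw minibatch losses are too noisy to define
#' a stall), validates periodically, stops early when the validation loss
#' diverges from its best, and returns the weights of the best validation
#' checkpoint. Fully deterministic given `config$seed`.
#'
#' @param model A `tam_model` (with an embedding head for the instance
#'   strategy).
#' @param train_set,val_set Lists of samples (`image`, `truth`, ...).
#' @param config A [train_config()].
#' @param verbose Print periodic progress lines.
#' @return `list(model, log)` where `log` is a data.frame with columns
#'   `iter`, `train_loss`, `val_loss` (NA between checks), `lr`.
#' @export
train <- function(model, train_set, val_set, config, verbose = FALSE) {
  stopifnot(inherits(config, "train_config"), length(train_set) > 0, length(val_set) > 0)
  if (config$strategy == "instance" && is.null(model$nodes$embedding))
    stop("train: instance strategy requires a model with an embedding decoder")
  set.seed(config$seed)
  # weight maps depend only on the truth; compute once per tile up front
  if (config$strategy == "weighted") {
    train_set <- lapply(train_set, function(s) {
      if (is.null(s$weight_map))
        s$weight_map <- do.call(compute_weight_map, c(list(s$truth), config$weight_map_args))
      s
    })
    val_set <- lapply(val_set, function(s) {
      if (is.null(s$weight_map))
        s$weight_map <- do.call(compute_weight_map, c(list(s$truth), config$weight_map_args))
      s
    })
  }
  opt <- adam_new(model$net, lr = config$learning_rate)
  sched <- lr_schedule_step(NULL, NULL, lr = config$learning_rate,
                            factor = config$lr_decay_factor,
                            patience = config$plateau_patience,
                            eps = config$improve_eps,
                            min_lr = config$min_lr %||% 0)
  loss_ema <- NULL  # plateau detection watches a smoothed loss: raw
                    # minibatch losses are too noisy to define a stall
  log <- data.frame(iter = integer(), train_loss = numeric(),
                    val_loss = numeric(), lr = numeric())
  best_val <- Inf
  best_weights <- nn_get_weights(model$net)
  diverge_count <- 0L

  val_loss_fn <- function() {
    tot <- 0
    for (s in val_set) {
      sp <- if (dim(s$image)[1] > config$patch_size ||
                dim(s$image)[2] > config$patch_size)
        sample_patch(s, config$patch_size) else s
      fwd <- model_forward_full(model, sp$image)
      tot <- tot + sample_loss_grads(model, fwd, sp, config)$loss
    }
    tot / length(val_set)
  }

  for (it in seq_len(config$max_iters)) {
    idx <- sample.int(length(train_set), min(config$batch_size, length(train_set)))
    batch_loss <- 0
    for (i in idx) {
      s <- prepare_sample(train_set[[i]], config)
      fwd <- model_forward_full(model, s$image)
      lg <- sample_loss_grads(model, fwd, s, config)
      if (!is.finite(lg$loss))
        stop(sprintf("train: non-finite loss at iteration %d (lr %.3g)", it, opt$lr))
      batch_loss <- batch_loss + lg$loss
      # scale gradients by 1/batch for a mean-over-batch objective
      lg$grads <- lapply(lg$grads, function(g) g / length(idx))
      nn_backward_accumulate(model$net, fwd, lg$grads, reset = (i == idx[1]))
    }
    batch_loss <- batch_loss / length(idx)
    adam_step(opt)
    loss_ema <- if (is.null(loss_ema)) batch_loss else 0.9 * loss_ema + 0.1 * batch_loss
    sched <- lr_schedule_step(sched, loss_ema)
    opt$lr <- sched$lr

    vl <- NA_real_
    if (it %% config$val_every == 0L || it == config$max_iters) {
      vl <- val_loss_fn()
      if (vl < best_val) {
        best_val <- vl
        best_weights <- nn_get_weights(model$net)
        diverge_count <- 0L
      } else if (vl > best_val * (1 + config$early_stop_margin)) {
        diverge_count <- diverge_count + 1L
      } else diverge_count <- 0L
      if (verbose)
        message(sprintf("iter %4d  train %.4f  val %.4f  lr %.2g", it, batch_loss, vl, opt$lr))
    }
    log <- rbind(log, data.frame(iter = it, train_loss = batch_loss,
                                 val_loss = vl, lr = opt$lr))
    if (diverge_count >= config$early_stop_patience) break
  }
  nn_set_weights(model$net, best_weights)
  list(model = model, log = log)
}

# Accumulating variant of nn_backward: parameter gradients from successive
# samples of a batch are summed (reset on the first sample).
nn_backward_accumulate <- function(net, fwd, grads_out, reset = FALSE) {
  if (reset) for (p in nn_params(net)) { p$acc_gw <- NULL; p$acc_gb <- NULL }
  nn_backward(net, fwd, grads_out)
  for (p in nn_params(net)) {
    if (!is.null(p$gw)) {
      p$acc_gw <- add_grad(p$acc_gw, p$gw)
      p$acc_gb <- add_grad(p$acc_gb, p$gb)
    }
  }
  for (p in nn_params(net)) { p$gw <- p$acc_gw; p$gb <- p$acc_gb }
  invisible(NULL)
}

#' Write a training log CSV
#' @param log Training log data.frame from [train()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_training_log <- function(log, path) {
  utils::write.csv(log, path, row.names = FALSE)
  invisible(path)
}
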