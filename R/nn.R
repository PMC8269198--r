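# A minimal define-by-construction computation graph for small encoder-decoder
# segmentation networks. Nodes are appended in topological order; backward
# walks them in reverse. Tensors are column-major arrays dim (H, W, C, N).
# Convolution/pooling/resampling kernels live in src/kernels.cpp.

nn_new <- function() {
  net <- new.env(parent = emptyenv())
  net$nodes <- list()
  net$outputs <- list()
  net
}

nn_add <- function(net, op, inputs = integer(0), params = NULL, args = list()) {
  # force all arguments before taking the next id: `inputs` is often a nested
  # nn_* call that itself appends nodes
  inputs <- as.integer(inputs); force(params); force(args)
  id <- length(net$nodes) + 1L
  net$nodes[[id]] <- list(id = id, op = op, inputs = inputs,
                          params = params, args = args)
  id
}

# He-initialized convolution parameters kept in an environment so Adam can
# update them in place.
conv_params <- function(kh, kw, cin_g, cout) {
  p <- new.env(parent = emptyenv())
  p$w <- array(stats::rnorm(kh * kw * cin_g * cout, 0,
                            sqrt(2 / (kh * kw * cin_g))), c(kh, kw, cin_g, cout))
  p$b <- numeric(cout)
  p
}

nn_conv <- function(net, input, cin, cout, k = 3L, stride = 1L, dil = 1L,
                    groups = 1L, pad = NULL) {
  if (is.null(pad)) pad <- dil * (k - 1L) %/% 2L
  params <- conv_params(k, k, cin %/% groups, cout)
  nn_add(net, "conv", input, params,
         list(stride = as.integer(stride), pad = as.integer(pad),
              dil = as.integer(dil), groups = as.integer(groups)))
}

nn_relu <- function(net, input) nn_add(net, "relu", input)
nn_maxpool <- function(net, input) nn_add(net, "maxpool", input)
nn_unpool <- function(net, input, pool_id) nn_add(net, "unpool", input, args = list(pool = pool_id))
nn_up_nearest <- function(net, input) nn_add(net, "up_nearest", input)
nn_up_bilinear_like <- function(net, input, ref) nn_add(net, "up_bilinear", input, args = list(ref = as.integer(ref)))
nn_concat <- function(net, inputs) nn_add(net, "concat", inputs)
# two normalized coordinate channels shaped like the ref node's output
nn_coords <- function(net, ref) nn_add(net, "coords", ref)
nn_add_op <- function(net, a, b) nn_add(net, "add", c(a, b))

# Forward pass; returns per-node activations plus pooling argmax caches.
nn_forward <- function(net, x) {
  vals <- vector("list", length(net$nodes))
  caches <- vector("list", length(net$nodes))
  for (node in net$nodes) {
    v <- switch(node$op,
      input = x,
      conv = .cpp_conv2d_fwd(vals[[node$inputs]], node$params$w, node$params$b,
                             node$args$stride, node$args$pad, node$args$dil,
                             node$args$groups),
      relu = { a <- vals[[node$inputs]]; a[a < 0] <- 0; a },
      maxpool = { r <- .cpp_maxpool2_fwd(vals[[node$inputs]])
                  caches[[node$id]] <- r$idx; r$y },
      unpool = { ref <- dim(vals[[net$nodes[[node$args$pool]]$inputs]])
                 .cpp_maxunpool2_fwd(vals[[node$inputs]], caches[[node$args$pool]],
                                     ref[1], ref[2]) },
      up_nearest = .cpp_upsample_nearest2_fwd(vals[[node$inputs]]),
      up_bilinear = { ref <- dim(vals[[node$args$ref]])
                      .cpp_upsample_bilinear_fwd(vals[[node$inputs]], ref[1], ref[2]) },
      coords = { d <- dim(vals[[node$inputs]])
                 out <- array(0, c(d[1], d[2], 2L, d[4]))
                 ych <- matrix(seq_len(d[1]) / d[1], d[1], d[2])
                 xch <- matrix(rep(seq_len(d[2]) / d[2], each = d[1]), d[1], d[2])
                 for (n in seq_len(d[4])) { out[, , 1L, n] <- ych; out[, , 2L, n] <- xch }
                 out },
      concat = { parts <- vals[node$inputs]
                 d <- dim(parts[[1]])
                 ctot <- sum(vapply(parts, function(p) dim(p)[3], numeric(1)))
                 out <- array(0, c(d[1], d[2], ctot, d[4]))
                 off <- 0L
                 for (p in parts) { cc <- dim(p)[3]
                   out[, , off + seq_len(cc), ] <- p; off <- off + cc }
                 out },
      add = vals[[node$inputs[1]]] + vals[[node$inputs[2]]],
      stop("nn_forward: unknown op ", node$op))
    vals[[node$id]] <- v
  }
  list(vals = vals, caches = caches)
}

# Backward pass. `grads_out` is a named list node_id -> gradient array for the
# requested output nodes. Parameter gradients are accumulated into each conv's
# params environment ($gw, $gb); returns nothing useful beyond that.
nn_backward <- function(net, fwd, grads_out) {
  vals <- fwd$vals
  dvals <- vector("list", length(net$nodes))
  for (nm in names(grads_out)) {
    id <- as.integer(nm)
    dvals[[id]] <- add_grad(dvals[[id]], grads_out[[nm]])
  }
  for (p in nn_params(net)) { p$gw <- NULL; p$gb <- NULL }
  for (node in rev(net$nodes)) {
    g <- dvals[[node$id]]
    if (is.null(g)) next
    switch(node$op,
      input = NULL,
      coords = NULL,  # constant field: no gradient to propagate
      conv = {
        r <- .cpp_conv2d_bwd(vals[[node$inputs]], node$params$w, g,
                             node$args$stride, node$args$pad, node$args$dil,
                             node$args$groups)
        node$params$gw <- add_grad(node$params$gw, r$dw)
        node$params$gb <- add_grad(node$params$gb, r$db)
        dvals[[node$inputs]] <- add_grad(dvals[[node$inputs]], r$dx)
      },
      relu = {
        d <- g; d[vals[[node$inputs]] <= 0] <- 0
        dvals[[node$inputs]] <- add_grad(dvals[[node$inputs]], d)
      },
      maxpool = {
        ref <- dim(vals[[node$inputs]])
        dvals[[node$inputs]] <- add_grad(dvals[[node$inputs]],
          .cpp_maxpool2_bwd(g, fwd$caches[[node$id]], ref[1], ref[2]))
      },
      unpool = {
        d_in <- dim(vals[[node$inputs]])
        dvals[[node$inputs]] <- add_grad(dvals[[node$inputs]],
          .cpp_maxunpool2_bwd(g, fwd$caches[[node$args$pool]], d_in[1], d_in[2]))
      },
      up_nearest = {
        dvals[[node$inputs]] <- add_grad(dvals[[node$inputs]],
          .cpp_upsample_nearest2_bwd(g))
      },
      up_bilinear = {
        ref <- dim(vals[[node$inputs]])
        dvals[[node$inputs]] <- add_grad(dvals[[node$inputs]],
          .cpp_upsample_bilinear_bwd(g, ref[1], ref[2]))
      },
      concat = {
        off <- 0L
        for (inp in node$inputs) {
          cc <- dim(vals[[inp]])[3]
          dvals[[inp]] <- add_grad(dvals[[inp]], g[, , off + seq_len(cc), , drop = FALSE])
          off <- off + cc
        }
      },
      add = {
        dvals[[node$inputs[1]]] <- add_grad(dvals[[node$inputs[1]]], g)
        dvals[[node$inputs[2]]] <- add_grad(dvals[[node$inputs[2]]], g)
      })
    dvals[[node$id]] <- NULL  # free early
  }
  invisible(NULL)
}

add_grad <- function(acc, g) if (is.null(acc)) g else acc + g

# All parameter environments of a network, in node order.
nn_params <- function(net) {
  ps <- list()
  for (node in net$nodes) if (!is.null(node$params)) ps[[length(ps) + 1L]] <- node$params
  ps
}

nn_param_count <- function(net) {
  sum(vapply(nn_params(net), function(p) length(p$w) + length(p$b), numeric(1)))
}

# Restrict to the parameters feeding a given output node (used to keep the
# duplicated decoder independently optimized and to test gradient isolation).
nn_ancestor_params <- function(net, out_id) {
  seen <- logical(length(net$nodes))
  stack <- out_id
  while (length(stack)) {
    id <- stack[[1]]; stack <- stack[-1]
    if (seen[id]) next
    seen[id] <- TRUE
    stack <- c(stack, net$nodes[[id]]$inputs)
  }
  ps <- list()
  for (node in net$nodes)
    if (seen[node$id] && !is.null(node$params)) ps[[length(ps) + 1L]] <- node$params
  ps
}

# --- Adam optimizer ---------------------------------------------------------

adam_new <- function(net, lr = 1e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt <- new.env(parent = emptyenv())
  opt$params <- nn_params(net)
  opt$lr <- lr; opt$beta1 <- beta1; opt$beta2 <- beta2; opt$eps <- eps
  opt$t <- 0L
  for (p in opt$params) {
    p$mw <- array(0, dim(p$w)); p$vw <- array(0, dim(p$w))
    p$mb <- numeric(length(p$b)); p$vb <- numeric(length(p$b))
  }
  opt
}

adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (p in opt$params) {
    if (is.null(p$gw)) next
    p$mw <- opt$beta1 * p$mw + (1 - opt$beta1) * p$gw
    p$vw <- opt$beta2 * p$vw + (1 - opt$beta2) * p$gw^2
    p$w <- p$w - opt$lr * (p$mw / bc1) / (sqrt(p$vw / bc2) + opt$eps)
    p$mb <- opt$beta1 * p$mb + (1 - opt$beta1) * p$gb
    p$vb <- opt$beta2 * p$vb + (1 - opt$beta2) * p$gb^2
    p$b <- p$b - opt$lr * (p$mb / bc1) / (sqrt(p$vb / bc2) + opt$eps)
  }
  invisible(opt)
}

# Serialize / restore all parameters as plain arrays.
nn_get_weights <- function(net) lapply(nn_params(net), function(p) list(w = p$w, b = p$b))
nn_set_weights <- function(net, ws) {
  ps <- nn_params(net)
  stopifnot(length(ps) == length(ws))
  for (i in seq_along(ps)) { ps[[i]]$w <- ws[[i]]$w; ps[[i]]$b <- ws[[i]]$b }
  invisible(net)
}
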