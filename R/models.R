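#' Segmentation model configuration
#'
#' Describes one encoder–decoder network from the three supported families.
#' All families map an RGB patch to per-pixel class scores at full input
#' resolution; the instance variant adds a structurally identical, duplicated
#' decoder branch emitting an n-dimensional pixel embedding.
#'
#' `base_channels` is a width multiplier: small values give desk-scale,
#' CPU-trainable variants (a `base_channels = 4` network has well under 1e5
#' parameters), larger values approach the full-size architectures.
#'
#' @param family One of `"unet"`, `"segnet"`, `"deeplabv3"`.
#' @param base_channels Width multiplier (>= 4, default 8).
#' @param depth Encoder depth: number of 2x downsampling stages for
#'   unet/segnet (default 2); deeplabv3 always works at output stride 4 with
#'   atrous convolutions beyond that.
#' @param num_classes Number of semantic classes (2: background/foreground).
#' @param embedding_dim Embedding dimensionality for the instance variant, or
#'   `NULL` for semantic-only models.
#' @param backbone For deeplabv3: `"simple"` (plain strided convolutions) or
#'   `"mobilenetv2_style"` (inverted-residual blocks with depthwise
#'   convolutions, reimplemented at configurable width; no pretrained
#'   weights).
#' @param use_coords Append two normalized pixel-coordinate channels to the
#'   network input. Defaults to `TRUE` when an embedding head is requested
#'   (position information is what lets the embedding branch assign nearby
#'   look-alike pixels to different instances) and `FALSE` otherwise.
#' @param aspp_rates Dilation rates of the three parallel atrous branches in
#'   the deeplabv3 family (default `c(1, 2, 4)` at the network's stride-4
#'   feature resolution; larger rates widen the receptive field for bigger
#'   cells).
#' @return A `model_config` list.
#' @export
model_config <- function(family = c("deeplabv3", "unet", "segnet"),
                         base_channels = 8L, depth = 2L, num_classes = 2L,
                         embedding_dim = NULL, backbone = c("simple", "mobilenetv2_style"),
                         use_coords = NULL, aspp_rates = c(1L, 2L, 4L)) {
  family <- match.arg(family)
  backbone <- match.arg(backbone)
  if (base_channels < 4L) stop("model_config: base_channels must be >= 4")
  if (!is.null(embedding_dim) && embedding_dim < 2L)
    stop("model_config: embedding_dim must be >= 2")
  if (is.null(use_coords)) use_coords <- !is.null(embedding_dim)
  structure(list(family = family, base_channels = as.integer(base_channels),
                 depth = as.integer(depth), num_classes = as.integer(num_classes),
                 embedding_dim = if (is.null(embedding_dim)) NULL else as.integer(embedding_dim),
                 backbone = backbone, use_coords = isTRUE(use_coords),
                 aspp_rates = as.integer(aspp_rates)),
            class = "model_config")
}

#' Build a segmentation network
#'
#' Constructs the requested family at the configured width. The returned
#' model carries a decoder factory so that [add_embedding_decoder()] can
#' append a second, independently parameterized copy of the decoder for the
#' instance variant. If `config$embedding_dim` is set the embedding decoder
#' is attached immediately. Weight initialization consumes the current RNG
#' stream (He-normal), so `set.seed()` before building gives reproducible
#' weights.
#'
#' @param config A [model_config()].
#' @return A `tam_model`: list with the computation graph, the config, the
#'   output node ids and the decoder factory.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  cin <- 3L + if (config$use_coords) 2L else 0L
  builder <- switch(config$family,
                    unet = build_unet, segnet = build_segnet,
                    deeplabv3 = build_deeplab)
  model <- builder(config, cin)
  model$config <- config
  class(model) <- "tam_model"
  if (!is.null(config$embedding_dim))
    model <- add_embedding_decoder(model, config$embedding_dim)
  model
}

#' Attach a duplicated embedding decoder
#'
#' Appends a structurally identical, independently parameterized copy of the
#' model's decoder branch that emits per-pixel `embedding_dim`-dimensional
#' vectors. The semantic head and its parameters are untouched; gradients of
#' losses on the embedding output never reach semantic-decoder-exclusive
#' parameters (and vice versa), since the two branches only share the
#' encoder.
#'
#' @param model A `tam_model` from [build_model()].
#' @param embedding_dim Embedding dimensionality (>= 2).
#' @return The model with `nodes$embedding` set.
#' @export
add_embedding_decoder <- function(model, embedding_dim) {
  if (embedding_dim < 2L) stop("add_embedding_decoder: embedding_dim must be >= 2")
  n_before <- length(nn_params(model$net))
  # the duplicate decoder also receives coordinate channels at its input
  # (when the model uses coordinate features at all): separating identical-
  # looking adjacent cells requires decoding position, not only appearance
  model$nodes$embedding <- model$decoder_factory(as.integer(embedding_dim),
                                                 with_coords = model$config$use_coords)
  model$config$embedding_dim <- as.integer(embedding_dim)
  # near-zero init of the embedding head: initial embeddings start collapsed,
  # keeping early push/pull hinge violations (and their gradients into the
  # shared encoder) small
  new_params <- nn_params(model$net)
  head <- new_params[[length(new_params)]]
  if (length(new_params) > n_before) head$w <- head$w * 0.01
  model
}

# ---- family builders -------------------------------------------------------

conv_block <- function(net, input, cin, cout, n = 2L) {
  for (i in seq_len(n)) {
    input <- nn_relu(net, nn_conv(net, input, cin, cout))
    cin <- cout
  }
  input
}

build_unet <- function(config, cin) {
  net <- nn_new()
  c0 <- config$base_channels; D <- config$depth
  input <- nn_add(net, "input")
  skips <- integer(D); chans <- integer(D)
  cur <- input; cc <- cin
  for (d in seq_len(D)) {
    ch <- c0 * 2^(d - 1)
    cur <- conv_block(net, cur, cc, ch)
    skips[d] <- cur; chans[d] <- ch
    cur <- nn_maxpool(net, cur)
    cc <- ch
  }
  bott_ch <- c0 * 2^D
  bott <- conv_block(net, cur, cc, bott_ch)
  decoder_factory <- function(out_ch, with_coords = FALSE, up = "bilinear") {
    cur <- bott; cc <- bott_ch
    if (with_coords) {
      cur <- nn_concat(net, c(cur, nn_coords(net, cur)))
      cc <- cc + 2L
    }
    for (d in rev(seq_len(D))) {
      cur <- nn_up_nearest(net, cur)
      cur <- nn_concat(net, c(cur, skips[d]))
      cur <- conv_block(net, cur, cc + chans[d], chans[d])
      cc <- chans[d]
    }
    nn_conv(net, cur, cc, out_ch, k = 1L)
  }
  sem <- decoder_factory(config$num_classes)
  list(net = net, nodes = list(input = input, semantic = sem, embedding = NULL),
       decoder_factory = decoder_factory, stride = 2^D)
}

build_segnet <- function(config, cin) {
  net <- nn_new()
  c0 <- config$base_channels; D <- config$depth
  input <- nn_add(net, "input")
  pools <- integer(D); chans <- integer(D)
  cur <- input; cc <- cin
  for (d in seq_len(D)) {
    ch <- c0 * 2^(d - 1)
    cur <- conv_block(net, cur, cc, ch)
    cur <- nn_maxpool(net, cur)
    pools[d] <- cur; chans[d] <- ch
    cc <- ch
  }
  decoder_factory <- function(out_ch, with_coords = FALSE, up = "bilinear") {
    cur2 <- cur; cc2 <- cc
    if (with_coords) {
      cur2 <- nn_concat(net, c(cur2, nn_coords(net, cur2)))
      cc2 <- cc2 + 2L
    }
    for (d in rev(seq_len(D))) {
      cur2 <- nn_unpool(net, cur2, pools[d])
      ch <- if (d > 1) chans[d - 1] else c0
      cur2 <- conv_block(net, cur2, cc2, ch)
      cc2 <- ch
    }
    nn_conv(net, cur2, cc2, out_ch, k = 1L)
  }
  sem <- decoder_factory(config$num_classes)
  list(net = net, nodes = list(input = input, semantic = sem, embedding = NULL),
       decoder_factory = decoder_factory, stride = 2^D)
}

inverted_residual <- function(net, input, cin, cout, expand = 4L, stride = 1L) {
  mid <- cin * expand
  cur <- nn_relu(net, nn_conv(net, input, cin, mid, k = 1L))
  cur <- nn_relu(net, nn_conv(net, cur, mid, mid, k = 3L, stride = stride, groups = mid))
  cur <- nn_conv(net, cur, mid, cout, k = 1L)
  if (stride == 1L && cin == cout) cur <- nn_add_op(net, cur, input)
  cur
}

build_deeplab <- function(config, cin) {
  net <- nn_new()
  c0 <- config$base_channels
  input <- nn_add(net, "input")
  if (config$backbone == "simple") {
    cur <- nn_relu(net, nn_conv(net, input, cin, c0))
    cur <- nn_relu(net, nn_conv(net, cur, c0, 2L * c0, stride = 2L))
    cur <- nn_relu(net, nn_conv(net, cur, 2L * c0, 2L * c0))
    cur <- nn_relu(net, nn_conv(net, cur, 2L * c0, 4L * c0, stride = 2L))
    feat <- cur; fch <- 4L * c0
  } else {
    cur <- nn_relu(net, nn_conv(net, input, cin, c0, stride = 2L))
    cur <- inverted_residual(net, cur, c0, 2L * c0, stride = 2L)
    cur <- nn_relu(net, cur)
    cur <- inverted_residual(net, cur, 2L * c0, 2L * c0, stride = 1L)
    cur <- nn_relu(net, cur)
    feat <- cur; fch <- 2L * c0
  }
  # atrous spatial pyramid: parallel dilated 3x3 branches
  rates <- config$aspp_rates %||% c(1L, 2L, 4L)
  b1 <- nn_relu(net, nn_conv(net, feat, fch, c0, dil = rates[1]))
  b2 <- nn_relu(net, nn_conv(net, feat, fch, c0, dil = rates[2]))
  b3 <- nn_relu(net, nn_conv(net, feat, fch, c0, dil = rates[3]))
  aspp <- nn_relu(net, nn_conv(net, nn_concat(net, c(b1, b2, b3)), 3L * c0, 2L * c0, k = 1L))
  decoder_factory <- function(out_ch, with_coords = FALSE, up = "bilinear") {
    src <- aspp; sc <- 2L * c0
    if (with_coords) {
      src <- nn_concat(net, c(src, nn_coords(net, src)))
      sc <- sc + 2L
    }
    cur <- nn_relu(net, nn_conv(net, src, sc, 2L * c0))
    cur <- nn_relu(net, nn_conv(net, cur, 2L * c0, c0))
    head <- nn_conv(net, cur, c0, out_ch, k = 1L)
    if (up == "nearest") {
      # crisp 4x upsampling: embedding fields must not blend across the
      # boundary between adjacent instances the way bilinear output does
      nn_up_nearest(net, nn_up_nearest(net, head))
    } else {
      nn_up_bilinear_like(net, head, input)
    }
  }
  sem <- decoder_factory(config$num_classes)
  list(net = net, nodes = list(input = input, semantic = sem, embedding = NULL),
       decoder_factory = decoder_factory, stride = 4L)
}

# ---- forward ---------------------------------------------------------------

# Append normalized row/column coordinate channels (in [0, 1]) to a batch.
with_coords <- function(x) {
  d <- dim(x)
  ych <- matrix(seq_len(d[1]) / d[1], d[1], d[2])
  xch <- matrix(rep(seq_len(d[2]) / d[2], each = d[1]), d[1], d[2])
  out <- array(0, c(d[1], d[2], d[3] + 2L, d[4]))
  out[, , seq_len(d[3]), ] <- x
  for (n in seq_len(d[4])) { out[, , d[3] + 1L, n] <- ych; out[, , d[3] + 2L, n] <- xch }
  out
}

as_batch <- function(image) {
  if (length(dim(image)) == 3L) array(image, c(dim(image), 1L)) else image
}

# Full forward returning the graph activations (needed for training).
model_forward_full <- function(model, image) {
  x <- as_batch(image)
  d <- dim(x)
  if (d[1] %% model$stride != 0L || d[2] %% model$stride != 0L)
    stop(sprintf("model input %dx%d must be divisible by the network stride %d",
                 d[1], d[2], model$stride))
  if (model$config$use_coords) x <- with_coords(x)
  fwd <- nn_forward(model$net, x)
  fwd
}

#' Run a model on an image
#'
#' @param model A `tam_model`.
#' @param image An `H x W x 3` array in \[0,1\] (or an `H x W x 3 x N` batch).
#'   Height and width must be divisible by the network stride.
#' @return `list(class_scores = H x W x 2 array of logits, embeddings =
#'   H x W x n array or NULL)`; batched inputs keep their batch dimension.
#' @export
model_forward <- function(model, image) {
  single <- length(dim(image)) == 3L
  fwd <- model_forward_full(model, image)
  cs <- fwd$vals[[model$nodes$semantic]]
  emb <- if (!is.null(model$nodes$embedding)) fwd$vals[[model$nodes$embedding]] else NULL
  if (single) {
    cs <- array(cs, dim(cs)[1:3])
    if (!is.null(emb)) emb <- array(emb, dim(emb)[1:3])
  }
  list(class_scores = cs, embeddings = emb)
}

#' Save / load model checkpoints
#'
#' Checkpoints are RDS files bundling the weights with a JSON manifest of the
#' [model_config()], so a checkpoint is self-describing and reproducible.
#'
#' @param model A `tam_model`.
#' @param path Checkpoint file path (`.rds`).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the rebuilt model.
#' @export
save_checkpoint <- function(model, path) {
  cfg <- model$config
  manifest <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, null = "null")
  saveRDS(list(manifest = as.character(manifest),
               weights = nn_get_weights(model$net)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- jsonlite::fromJSON(ck$manifest)
  config <- model_config(family = cfg$family, base_channels = cfg$base_channels,
                         depth = cfg$depth, num_classes = cfg$num_classes,
                         embedding_dim = cfg$embedding_dim, backbone = cfg$backbone,
                         use_coords = cfg$use_coords,
                         aspp_rates = if (is.null(cfg$aspp_rates)) c(1L, 2L, 4L)
                                      else cfg$aspp_rates)
  model <- build_model(config)
  nn_set_weights(model$net, ck$weights)
  model
}
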