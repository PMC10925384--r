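#' 3D U-Net configuration
#'
#' An encoder-decoder with skip connections: each resolution level applies
#' two 3x3x3 convolutions with leaky-ReLU activations; levels are connected
#' by 2x max-pooling on the way down and nearest-neighbor upsampling on the
#' way up (the first convolution after each upsampling plays the role of the
#' learned upsampling filter). A final 1x1x1 projection emits either two
#' softmax channels (brain, background) or one linear channel predicting a
#' signed distance transform. Feature widths double per level up to
#' `channel_cap`.
#'
#' The full-scale preset mirrors the published skull-stripping architecture
#' (seven levels); examples and tests run 3-4 levels on small grids.
#'
#' @param n_levels number of resolution levels (>= 1).
#' @param base_channels feature channels at the first level.
#' @param channel_cap ceiling on per-level channels.
#' @param activation_slope negative slope of the leaky-ReLU.
#' @param output_mode `"softmax_2ch"` (mask) or `"sdt_1ch"` (distance).
#' @param precision `"double"` (default) or `"single"`: arithmetic of the
#'   convolution kernels. Single precision is ~1.5x faster and numerically
#'   ample for training; gradients are still verified in double.
#' @param convs_per_level fixed at 2.
#' @return A `unet_config`.
#' @export
unet_config <- function(n_levels = 3, base_channels = 16, channel_cap = 256,
                        activation_slope = 0.2,
                        output_mode = c("softmax_2ch", "sdt_1ch"),
                        precision = c("double", "single"),
                        convs_per_level = 2) {
  output_mode <- match.arg(output_mode)
  precision <- match.arg(precision)
  if (n_levels < 1) stop("n_levels must be >= 1")
  if (convs_per_level != 2) stop("the architecture uses 2 convolutions per level")
  if (base_channels < 1 || channel_cap < base_channels)
    stop("channel counts must be positive with channel_cap >= base_channels")
  structure(list(n_levels = as.integer(n_levels),
                 base_channels = as.integer(base_channels),
                 channel_cap = as.integer(channel_cap),
                 activation_slope = activation_slope,
                 output_mode = output_mode, precision = precision,
                 convs_per_level = 2L),
            class = "unet_config")
}

#' @rdname unet_config
#' @export
unet_config_fullscale <- function() unet_config(n_levels = 7, base_channels = 16,
                                                channel_cap = 256)

.unet_channels <- function(config)
  pmin(config$base_channels * 2^(seq_len(config$n_levels) - 1),
       config$channel_cap)

.check_grid <- function(config, dims) {
  div <- 2^(config$n_levels - 1)
  bad <- which(dims %% div != 0)
  if (length(bad))
    stop(sprintf("grid size (%s) not divisible by %d as required at level %d",
                 paste(dims, collapse = "x"), div, config$n_levels))
}

.he_init <- function(cout, cin, k) {
  array(rnorm(cout * cin * k, 0, sqrt(2 / (cin * k))), c(cout, cin, k))
}

#' Build (initialize) U-Net parameters
#'
#' Deterministic given `seed`: identical configs and seeds yield identical
#' parameters. Weights use He initialization, biases start at zero.
#'
#' @param config a [unet_config()].
#' @param in_channels input image channels (1 for gray-scale volumes).
#' @param seed integer seed.
#' @return A `unet_params` object (list of weight arrays plus the config).
#' @export
build_unet <- function(config, in_channels = 1L, seed = 1L) {
  stopifnot(inherits(config, "unet_config"))
  ch <- .unet_channels(config)
  L <- config$n_levels
  set.seed(.sub_seed(seed, 51L))
  enc <- vector("list", L)
  cin <- in_channels
  for (i in seq_len(L)) {
    enc[[i]] <- list(
      conv1 = list(W = .he_init(ch[i], cin, 27L), b = numeric(ch[i])),
      conv2 = list(W = .he_init(ch[i], ch[i], 27L), b = numeric(ch[i])))
    cin <- ch[i]
  }
  dec <- if (L > 1) lapply(rev(seq_len(L - 1)), function(i) list(
    conv1 = list(W = .he_init(ch[i], ch[i] + ch[i + 1], 27L),
                 b = numeric(ch[i])),
    conv2 = list(W = .he_init(ch[i], ch[i], 27L), b = numeric(ch[i]))))
  else list()
  cf <- if (config$output_mode == "softmax_2ch") 2L else 1L
  # near-zero projection head: keeps early softmax outputs close to uniform
  # so the minority (brain) channel cannot saturate to zero before the
  # feature pathways have learned anything
  final <- list(W = matrix(rnorm(cf * ch[1], 0, 0.01), cf, ch[1]),
                b = numeric(cf))
  structure(list(config = config, in_channels = as.integer(in_channels),
                 enc = enc, dec = dec, final = final),
            class = "unet_params")
}

#' Number of trainable parameters
#'
#' @param params a `unet_params`, or a [unet_config()] (with `in_channels`).
#' @param in_channels input channels when `params` is a config.
#' @return integer parameter count.
#' @export
n_unet_params <- function(params, in_channels = 1L) {
  if (inherits(params, "unet_config"))
    params <- build_unet(params, in_channels)
  sum(vapply(.flatten_params(params), length, integer(1)))
}

# depth-first list of numeric arrays making up the parameters
.flatten_params <- function(params) {
  out <- list()
  for (i in seq_along(params$enc)) {
    out[[paste0("enc", i, ".W1")]] <- params$enc[[i]]$conv1$W
    out[[paste0("enc", i, ".b1")]] <- params$enc[[i]]$conv1$b
    out[[paste0("enc", i, ".W2")]] <- params$enc[[i]]$conv2$W
    out[[paste0("enc", i, ".b2")]] <- params$enc[[i]]$conv2$b
  }
  for (i in seq_along(params$dec)) {
    out[[paste0("dec", i, ".W1")]] <- params$dec[[i]]$conv1$W
    out[[paste0("dec", i, ".b1")]] <- params$dec[[i]]$conv1$b
    out[[paste0("dec", i, ".W2")]] <- params$dec[[i]]$conv2$W
    out[[paste0("dec", i, ".b2")]] <- params$dec[[i]]$conv2$b
  }
  out[["final.W"]] <- params$final$W
  out[["final.b"]] <- params$final$b
  out
}

.unflatten_params <- function(params, flat) {
  for (i in seq_along(params$enc)) {
    params$enc[[i]]$conv1$W <- flat[[paste0("enc", i, ".W1")]]
    params$enc[[i]]$conv1$b <- flat[[paste0("enc", i, ".b1")]]
    params$enc[[i]]$conv2$W <- flat[[paste0("enc", i, ".W2")]]
    params$enc[[i]]$conv2$b <- flat[[paste0("enc", i, ".b2")]]
  }
  for (i in seq_along(params$dec)) {
    params$dec[[i]]$conv1$W <- flat[[paste0("dec", i, ".W1")]]
    params$dec[[i]]$conv1$b <- flat[[paste0("dec", i, ".b1")]]
    params$dec[[i]]$conv2$W <- flat[[paste0("dec", i, ".W2")]]
    params$dec[[i]]$conv2$b <- flat[[paste0("dec", i, ".b2")]]
  }
  params$final$W <- flat[["final.W"]]
  params$final$b <- flat[["final.b"]]
  params
}

# weights rearranged for the input-gradient pass: transpose channels and
# flip the 27 taps
.flip_weights <- function(W) {
  aperm(W[, , 27:1, drop = FALSE], c(2, 1, 3))
}

.conv_fns <- function(config) {
  if (identical(config$precision, "single"))
    list(fwd = .conv3_fwd_f32, wb = .conv3_bwd_wb_f32)
  else list(fwd = .conv3_fwd, wb = .conv3_bwd_wb)
}

.conv_block_fwd <- function(x, layer, dims, slope, fns) {
  z1 <- fns$fwd(x, as.vector(layer$conv1$W), layer$conv1$b, dims)
  a1 <- .lrelu_fwd(z1, slope)
  z2 <- fns$fwd(a1, as.vector(layer$conv2$W), layer$conv2$b, dims)
  a2 <- .lrelu_fwd(z2, slope)
  list(x = x, z1 = z1, a1 = a1, z2 = z2, a2 = a2)
}

.conv_block_bwd <- function(cache, layer, dims, slope, g, fns,
                            need_input_grad = TRUE) {
  g <- .lrelu_bwd(cache$z2, g, slope)
  wb2 <- fns$wb(cache$a1, g, dims)
  g <- fns$fwd(g, as.vector(.flip_weights(layer$conv2$W)),
               numeric(nrow(cache$a1)), dims)
  g <- .lrelu_bwd(cache$z1, g, slope)
  wb1 <- fns$wb(cache$x, g, dims)
  gx <- if (need_input_grad)
    fns$fwd(g, as.vector(.flip_weights(layer$conv1$W)),
            numeric(nrow(cache$x)), dims)
  else NULL
  list(gx = gx, gW1 = wb1$gW, gb1 = wb1$gb, gW2 = wb2$gW, gb2 = wb2$gb)
}

#' U-Net forward pass
#'
#' @param params a `unet_params`.
#' @param x channels-by-voxels feature matrix (1 x N for gray-scale input).
#' @param dims length-3 grid size with `prod(dims) == ncol(x)`; every axis
#'   must be divisible by `2^(n_levels - 1)`.
#' @param cache keep intermediate activations for a backward pass.
#' @return list with `output` (softmax probabilities or linear SDT channel,
#'   channels x voxels) and, if requested, the `cache`.
#' @export
unet_forward <- function(params, x, dims, cache = FALSE) {
  config <- params$config
  .check_grid(config, dims)
  L <- config$n_levels
  slope <- config$activation_slope
  fns <- .conv_fns(config)
  dims_i <- as.integer(dims)

  enc_caches <- vector("list", L)
  pools <- vector("list", max(L - 1, 0))
  level_dims <- vector("list", L)
  cur <- x
  for (i in seq_len(L)) {
    level_dims[[i]] <- dims_i
    bc <- .conv_block_fwd(cur, params$enc[[i]], dims_i, slope, fns)
    enc_caches[[i]] <- bc
    if (i < L) {
      mp <- .maxpool2_fwd(bc$a2, dims_i)
      pools[[i]] <- mp
      cur <- mp$out
      dims_i <- dims_i %/% 2L
    } else cur <- bc$a2
  }

  dec_caches <- vector("list", length(params$dec))
  for (j in seq_along(params$dec)) {
    i <- L - j  # encoder level this decoder stage restores
    up <- .upsample2_fwd(cur, level_dims[[i + 1]])
    cat_in <- rbind(enc_caches[[i]]$a2, up)
    bc <- .conv_block_fwd(cat_in, params$dec[[j]], level_dims[[i]], slope,
                          fns)
    dec_caches[[j]] <- bc
    cur <- bc$a2
  }

  logits <- params$final$W %*% cur + params$final$b
  output <- if (config$output_mode == "softmax_2ch") .softmax2(logits) else logits

  res <- list(output = output, logits = logits)
  if (cache)
    res$cache <- list(enc = enc_caches, pools = pools, dec = dec_caches,
                      level_dims = level_dims, top = cur, x = x)
  res
}

.softmax2 <- function(logits) {
  m <- pmax(logits[1, ], logits[2, ])
  e1 <- exp(logits[1, ] - m)
  e2 <- exp(logits[2, ] - m)
  rbind(e1 / (e1 + e2), e2 / (e1 + e2))
}

# backward pass from the gradient wrt logits; returns flat gradient list
# keyed like .flatten_params()
.unet_backward <- function(params, fwd, g_logits) {
  config <- params$config
  L <- config$n_levels
  slope <- config$activation_slope
  fns <- .conv_fns(config)
  cache <- fwd$cache
  grads <- list()

  grads[["final.W"]] <- g_logits %*% t(cache$top)
  grads[["final.b"]] <- rowSums(g_logits)
  g <- crossprod(params$final$W, g_logits)  # wrt the topmost block output

  g_skip <- vector("list", L)
  for (j in rev(seq_along(params$dec))) {  # decoder stage j restores level L - j
    i <- L - j
    bb <- .conv_block_bwd(cache$dec[[j]], params$dec[[j]],
                          as.integer(cache$level_dims[[i]]), slope, g, fns)
    grads[[paste0("dec", j, ".W1")]] <- bb$gW1
    grads[[paste0("dec", j, ".b1")]] <- bb$gb1
    grads[[paste0("dec", j, ".W2")]] <- bb$gW2
    grads[[paste0("dec", j, ".b2")]] <- bb$gb2
    nskip <- nrow(cache$enc[[i]]$a2)
    g_skip[[i]] <- bb$gx[seq_len(nskip), , drop = FALSE]
    g <- .upsample2_bwd(bb$gx[-seq_len(nskip), , drop = FALSE],
                        as.integer(cache$level_dims[[i + 1]]))
  }

  # g is now the gradient wrt enc[[L]]'s output (the bottleneck)
  for (i in rev(seq_len(L))) {
    bb <- .conv_block_bwd(cache$enc[[i]], params$enc[[i]],
                          as.integer(cache$level_dims[[i]]), slope, g, fns,
                          need_input_grad = i > 1)
    grads[[paste0("enc", i, ".W1")]] <- bb$gW1
    grads[[paste0("enc", i, ".b1")]] <- bb$gb1
    grads[[paste0("enc", i, ".W2")]] <- bb$gW2
    grads[[paste0("enc", i, ".b2")]] <- bb$gb2
    if (i > 1)
      g <- .maxpool2_bwd(bb$gx, cache$pools[[i - 1]]$argmax,
                         prod(cache$level_dims[[i - 1]])) + g_skip[[i - 1]]
  }
  grads
}

#' Predict a brain mask
#'
#' The input image is min-max normalized (matching the synthesis pipeline's
#' output scale) and pushed through the network. In softmax mode the mask is
#' `P(brain) > threshold`; in SDT mode it is `predicted distance < 0` under
#' the negative-inside convention.
#'
#' @param params a `unet_params`.
#' @param image an [intensity_volume()] on a grid compatible with the
#'   network's level count.
#' @param threshold probability cutoff for softmax mode (default 0.5).
#' @return A [brain_mask()] on the image grid.
#' @export
predict_mask <- function(params, image, threshold = 0.5) {
  stopifnot(inherits(params, "unet_params"),
            inherits(image, "intensity_volume"))
  dims <- vol_dims(image)
  x <- matrix(.minmax(as.vector(image$data)), nrow = 1)
  out <- unet_forward(params, x, dims)$output
  m <- if (params$config$output_mode == "softmax_2ch")
    out[1, ] > threshold
  else out[1, ] < 0
  brain_mask(array(as.integer(m), dims), image$affine)
}

#' Predict the raw network output
#'
#' @inheritParams predict_mask
#' @return softmax mode: 2 x N probability matrix; SDT mode: a
#'   [distance_map()].
#' @export
predict_raw <- function(params, image) {
  dims <- vol_dims(image)
  x <- matrix(.minmax(as.vector(image$data)), nrow = 1)
  out <- unet_forward(params, x, dims)$output
  if (params$config$output_mode == "sdt_1ch")
    distance_map(array(out[1, ], dims), image$affine)
  else out
}

#' Skull-strip an image
#'
#' Voxelwise product of the image with its predicted brain mask.
#'
#' @inheritParams predict_mask
#' @return list with `stripped` ([intensity_volume()]) and `mask`
#'   ([brain_mask()]).
#' @export
skull_strip <- function(params, image, threshold = 0.5) {
  mask <- predict_mask(params, image, threshold)
  stripped <- intensity_volume(image$data * mask$data, image$affine)
  list(stripped = stripped, mask = mask)
}

#' Save and load training checkpoints
#'
#' A checkpoint bundles network parameters with the configurations that
#' produced them (and, from [train_unet()], the loss history).
#'
#' @param checkpoint list with at least `params`; typically the return value
#'   of [train_unet()].
#' @param path file path (`.rds`).
#' @return `load_checkpoint()` returns the checkpoint list.
#' @export
save_checkpoint <- function(checkpoint, path) {
  stopifnot(inherits(checkpoint$params, "unet_params"))
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  stopifnot(inherits(ck$params, "unet_params"))
  ck
}
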