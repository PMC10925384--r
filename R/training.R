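#' Training configuration
#'
#' Controls the synthesis-driven optimization: at every step one label map is
#' drawn (uniformly, seeded), a synthetic training pair is generated, the
#' ground-truth targets are derived, and one Adam update (batch size 1) is
#' taken. Validation runs on held-out acquired-style image/mask pairs every
#' `validation_interval` steps, always scoring `1 - Dice` of the thresholded
#' prediction so runs with different loss modes are comparable; training stops
#' when the validation loss fails to improve by more than `plateau_min_delta`
#' for `plateau_patience` consecutive validations, or at `max_steps`.
#'
#' @param loss_mode `"dice"`, `"usdt"` (unweighted SDT regression) or
#'   `"wsdt"` (boundary-weighted SDT regression).
#' @param learning_rate Adam learning rate.
#' @param lr_decay_steps halve-style decay interval in steps (0 = constant
#'   learning rate); after every `lr_decay_steps` steps the rate is
#'   multiplied by `lr_decay_factor`.
#' @param lr_decay_factor multiplicative decay applied each interval.
#' @param clip_grad_norm cap on the global gradient L2 norm (0 = no
#'   clipping); guards the optimization against occasional extreme synthetic
#'   pairs.
#' @param ema_decay exponential moving average factor for the evaluated
#'   (and returned) weights, debiased over steps; 0 disables averaging.
#'   Batch-1 training leaves substantial parameter noise that averaging
#'   removes at validation time.
#' @param swa_start step after which weights are accumulated into a uniform
#'   tail average (stochastic weight averaging); 0 disables it. The returned
#'   checkpoint is the tail average if it validates better than the best
#'   single checkpoint. Intended for the low-learning-rate phase, where the
#'   iterates orbit one basin and their mean beats any single draw.
#' @param max_steps maximum optimization steps.
#' @param validation_interval steps between validations.
#' @param plateau_patience validations without improvement before stopping.
#' @param plateau_min_delta minimum improvement that resets the patience.
#' @param b,h SDT loss down-weight factor and band half-width (mm).
#' @param adam_beta1,adam_beta2,adam_eps Adam moment parameters.
#' @param unet a [unet_config()] describing the network to train.
#' @param init_seed seed for parameter initialization.
#' @param seed master seed for the step-level randomness.
#' @return A `train_config`.
#' @export
train_config <- function(loss_mode = c("dice", "usdt", "wsdt"),
                         learning_rate = 1e-4, lr_decay_steps = 0L,
                         lr_decay_factor = 0.5, clip_grad_norm = 0,
                         ema_decay = 0, swa_start = 0L, max_steps = 2000L,
                         validation_interval = 50L, plateau_patience = 5L,
                         plateau_min_delta = 1e-4, b = 1e-3, h = 4,
                         adam_beta1 = 0.9, adam_beta2 = 0.999,
                         adam_eps = 1e-8, unet = unet_config(),
                         init_seed = 1L, seed = 1L) {
  loss_mode <- match.arg(loss_mode)
  if (b < 0 || b > 1) stop("b must be in [0, 1]")
  if (h < 0) stop("h must be >= 0")
  if (plateau_patience < 1) stop("plateau_patience must be >= 1")
  if (max_steps < 0) stop("max_steps must be >= 0")
  stopifnot(inherits(unet, "unet_config"))
  if (loss_mode == "dice" && unet$output_mode != "softmax_2ch")
    stop("dice loss requires output_mode = 'softmax_2ch'")
  if (loss_mode != "dice" && unet$output_mode != "sdt_1ch")
    stop("SDT losses require output_mode = 'sdt_1ch'")
  if (lr_decay_steps < 0 || lr_decay_factor <= 0 || lr_decay_factor > 1)
    stop("lr decay needs lr_decay_steps >= 0 and lr_decay_factor in (0, 1]")
  if (clip_grad_norm < 0) stop("clip_grad_norm must be >= 0")
  if (ema_decay < 0 || ema_decay >= 1) stop("ema_decay must be in [0, 1)")
  if (swa_start < 0) stop("swa_start must be >= 0")
  structure(list(loss_mode = loss_mode, learning_rate = learning_rate,
                 lr_decay_steps = as.integer(lr_decay_steps),
                 lr_decay_factor = lr_decay_factor,
                 clip_grad_norm = clip_grad_norm, ema_decay = ema_decay,
                 swa_start = as.integer(swa_start),
                 batch_size = 1L, max_steps = as.integer(max_steps),
                 validation_interval = as.integer(validation_interval),
                 plateau_patience = as.integer(plateau_patience),
                 plateau_min_delta = plateau_min_delta, b = b, h = h,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 adam_eps = adam_eps, unet = unet,
                 init_seed = as.integer(init_seed), seed = as.integer(seed)),
            class = "train_config")
}

# single Adam update on flat parameter/gradient lists
.adam_step <- function(flat, grads, state, lr, b1, b2, eps) {
  state$t <- state$t + 1
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  for (nm in names(flat)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    flat[[nm]] <- flat[[nm]] - lr * (state$m[[nm]] / corr1) /
      (sqrt(state$v[[nm]] / corr2) + eps)
  }
  list(flat = flat, state = state)
}

# validation always scores Dice against the reference mask so runs with
# different loss modes are comparable. Softmax networks average the soft
# Dice of the brain probability (graded, so plateau detection sees progress
# even while the thresholded mask is still empty) and the hard Dice of the
# thresholded mask (the deployment metric, so checkpoint selection tracks
# it); SDT networks use the Dice of the thresholded prediction.
.validate <- function(params, val_pairs) {
  mean(vapply(val_pairs, function(vp) {
    if (params$config$output_mode == "softmax_2ch") {
      p <- predict_raw(params, vp$image)[1, ]
      y <- as.numeric(as.vector(vp$mask$data))
      eps <- 1e-6
      soft <- (2 * sum(p * y) + eps) / (sum(p^2) + sum(y^2) + eps)
      ph <- as.numeric(p > 0.5)
      hard <- if (sum(ph) + sum(y) == 0) 1 else
        2 * sum(ph * y) / (sum(ph) + sum(y))
      1 - (soft + hard) / 2
    } else {
      1 - dice_metric(predict_mask(params, vp$image), vp$mask)
    }
  }, numeric(1)))
}

#' Train a skull-stripping U-Net on synthesized images
#'
#' Every optimization step draws one whole-head label map, synthesizes a
#' corrupted training image from a spatially augmented copy of it, derives
#' the ground-truth brain mask (and, in SDT modes, the signed distance
#' transform) from the augmented labels, and updates the network with one
#' Adam step against the configured loss. The run is deterministic given the
#' configuration seeds (single-threaded execution).
#'
#' @param labelmaps list of [label_map()] objects (training label maps).
#' @param val_pairs list of validation cases, each a list with `image`
#'   (an [intensity_volume()]) and `mask` (a [brain_mask()]).
#' @param synth a [synth_config()].
#' @param tc a [train_config()].
#' @param verbose print progress lines.
#' @return A checkpoint list: `params` (best-validation parameters),
#'   `final_params`, `history` (data frame: step, train_loss),
#'   `val_history` (data frame: step, val_loss), `best_val`, `best_step`,
#'   `synth`, `tc`.
#' @export
train_unet <- function(labelmaps, val_pairs, synth, tc, verbose = FALSE) {
  stopifnot(length(labelmaps) >= 1, length(val_pairs) >= 1,
            inherits(synth, "synth_config"), inherits(tc, "train_config"))
  for (lm in labelmaps) stopifnot(inherits(lm, "label_map"))
  for (vp in val_pairs) stopifnot(inherits(vp$image, "intensity_volume"),
                                  inherits(vp$mask, "brain_mask"))

  params <- build_unet(tc$unet, in_channels = 1L, seed = tc$init_seed)
  flat <- .flatten_params(params)
  state <- list(t = 0,
                m = lapply(flat, function(p) p * 0),
                v = lapply(flat, function(p) p * 0))

  use_ema <- tc$ema_decay > 0
  ema <- if (use_ema) lapply(flat, function(p) p * 0)
  swa_sum <- NULL
  swa_n <- 0L
  # debiased EMA of the weights; falls back to the raw weights when off
  eval_weights <- function(step) {
    if (!use_ema || step == 0L) return(flat)
    corr <- 1 - tc$ema_decay^step
    Map(function(e) e / corr, ema)
  }

  val0 <- .validate(params, val_pairs)
  val_history <- data.frame(step = 0L, val_loss = val0)
  best_val <- val0
  best_flat <- flat
  best_step <- 0L
  stall <- 0L
  history <- data.frame(step = integer(0), train_loss = numeric(0))

  step <- 0L
  while (step < tc$max_steps) {
    step <- step + 1L
    set.seed(.sub_seed(tc$seed, 60L + step))
    map_idx <- sample.int(length(labelmaps), 1L)
    pair_seed <- .sub_seed(tc$seed, 100000L + step)
    pair <- generate_training_pair(labelmaps[[map_idx]], synth, pair_seed)
    dims <- vol_dims(pair$image)
    mask <- derive_brain_mask(pair$labels)

    # same normalization the inference path applies
    x <- matrix(.minmax(as.vector(pair$image$data)), nrow = 1)
    fwd <- unet_forward(params, x, dims, cache = TRUE)

    if (tc$loss_mode == "dice") {
      target <- .mask_to_2ch(mask$data)
      loss <- dice_loss(target, fwd$output)
      g_out <- .dice_loss_grad(target, fwd$output)
      # softmax jacobian: dL/dz_i = p_i (g_i - sum_j g_j p_j)
      p <- fwd$output
      g_logits <- p * (g_out - rep(colSums(g_out * p), each = 2))
    } else {
      sdt <- compute_sdt(mask)
      target <- as.vector(sdt$data)
      pred <- fwd$output[1, ]
      loss <- sdt_loss(target, pred, tc$b, tc$h, mode = tc$loss_mode)
      g_logits <- matrix(.sdt_loss_grad(target, pred, tc$b, tc$h,
                                        tc$loss_mode), nrow = 1)
    }
    if (!is.finite(loss))
      stop(sprintf("non-finite loss at step %d (map %d, pair seed %d); rerun with these seeds to replay",
                   step, map_idx, pair_seed))
    history <- rbind(history, data.frame(step = step, train_loss = loss))

    grads <- .unet_backward(params, fwd, g_logits)
    if (tc$clip_grad_norm > 0) {
      gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
      if (gn > tc$clip_grad_norm)
        grads <- lapply(grads, function(g) g * (tc$clip_grad_norm / gn))
    }
    lr <- tc$learning_rate
    if (tc$lr_decay_steps > 0)
      lr <- lr * tc$lr_decay_factor^((step - 1) %/% tc$lr_decay_steps)
    upd <- .adam_step(flat, grads, state, lr,
                      tc$adam_beta1, tc$adam_beta2, tc$adam_eps)
    flat <- upd$flat
    state <- upd$state
    params <- .unflatten_params(params, flat)
    if (use_ema)
      ema <- Map(function(e, p) tc$ema_decay * e + (1 - tc$ema_decay) * p,
                 ema, flat)
    if (tc$swa_start > 0 && step >= tc$swa_start) {
      swa_sum <- if (is.null(swa_sum)) flat else Map(`+`, swa_sum, flat)
      swa_n <- swa_n + 1L
    }

    if (step %% tc$validation_interval == 0L || step == tc$max_steps) {
      ew <- eval_weights(step)
      vl <- .validate(.unflatten_params(params, ew), val_pairs)
      val_history <- rbind(val_history, data.frame(step = step, val_loss = vl))
      if (verbose)
        message(sprintf("step %d  train %.4f  val %.4f", step, loss, vl))
      if (vl < best_val - tc$plateau_min_delta) {
        best_val <- vl
        best_flat <- ew
        best_step <- step
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= tc$plateau_patience) break
      }
    }
  }

  swa_val <- NA_real_
  if (swa_n > 0L) {
    swa_flat <- Map(function(x) x / swa_n, swa_sum)
    swa_val <- .validate(.unflatten_params(params, swa_flat), val_pairs)
    if (swa_val < best_val) {
      best_val <- swa_val
      best_flat <- swa_flat
      best_step <- -1L  # marks the tail average
    }
  }

  list(params = .unflatten_params(params, best_flat),
       final_params = params, history = history, val_history = val_history,
       best_val = best_val, best_step = best_step, swa_val = swa_val,
       synth = synth, tc = tc)
}
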