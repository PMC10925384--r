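# Shared desk-scale training fixtures: phantoms, synthesis preset and a
# memoized training run per seed, so the end-to-end tests reuse one
# optimization instead of repeating it.

.desk_cache <- new.env(parent = emptyenv())

desk_phantom_set <- function() {
  if (is.null(.desk_cache$maps)) {
    .desk_cache$maps <- lapply(1:8, function(i)
      make_phantom_labelmap(desk_phantom_spec(seed = i)))
    .desk_cache$val <- unlist(lapply(9:11, function(i) {
      lm <- make_phantom_labelmap(desk_phantom_spec(seed = i))
      mask <- derive_brain_mask(lm)
      lapply(c("t1_like", "t2_like"), function(ct)
        list(image = make_phantom_image(lm, ct, noise_sd = 5, seed = i),
             mask = mask))
    }), recursive = FALSE)
    .desk_cache$holdout <- lapply(41:43, function(i) {
      lm <- make_phantom_labelmap(desk_phantom_spec(seed = i))
      list(image = make_phantom_image(lm, "t1_like", noise_sd = 5, seed = i),
           mask = derive_brain_mask(lm))
    })
  }
  list(maps = .desk_cache$maps, val = .desk_cache$val,
       holdout = .desk_cache$holdout)
}

desk_train_config <- function(seed, max_steps = 500) {
  train_config(loss_mode = "dice", learning_rate = 1e-3,
               lr_decay_steps = 150, clip_grad_norm = 0.5, swa_start = 350,
               max_steps = max_steps, validation_interval = 25,
               plateau_patience = 8, plateau_min_delta = 1e-4,
               unet = unet_config(n_levels = 3, base_channels = 8,
                                  precision = "single"),
               init_seed = seed, seed = seed)
}

# memoized end-to-end run; returns checkpoint plus held-out metrics
desk_run <- function(seed) {
  key <- paste0("run", seed)
  if (is.null(.desk_cache[[key]])) {
    fx <- desk_phantom_set()
    ck <- train_unet(fx$maps, fx$val, synth_config(preset = "desk"),
                     desk_train_config(seed))
    dice <- vapply(fx$holdout, function(h)
      dice_metric(predict_mask(ck$params, h$image), h$mask), numeric(1))
    .desk_cache[[key]] <- list(
      ck = ck, holdout_dice = dice,
      val0 = ck$val_history$val_loss[1], best_val = ck$best_val)
  }
  .desk_cache[[key]]
}
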