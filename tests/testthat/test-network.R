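test_that("network construction is deterministic and sized predictably", {
  cfg <- unet_config(n_levels = 3, base_channels = 4)
  p1 <- build_unet(cfg, seed = 7)
  p2 <- build_unet(cfg, seed = 7)
  f1 <- pedistrip:::.flatten_params(p1)
  f2 <- pedistrip:::.flatten_params(p2)
  expect_identical(lapply(f1, sum), lapply(f2, sum))
  expect_identical(f1, f2)

  # closed-form parameter arithmetic: channels 4, 8, 16
  count_conv <- function(cin, cout) 27 * cin * cout + cout
  expected <- count_conv(1, 4) + count_conv(4, 4) +      # enc1
    count_conv(4, 8) + count_conv(8, 8) +                # enc2
    count_conv(8, 16) + count_conv(16, 16) +             # enc3 (bottleneck)
    count_conv(8 + 16, 8) + count_conv(8, 8) +           # dec to level 2
    count_conv(4 + 8, 4) + count_conv(4, 4) +            # dec to level 1
    (2 * 4 + 2)                                          # 1x1x1 projection
  expect_equal(n_unet_params(p1), expected)
})

test_that("a single-level network is a plain convolution stack", {
  cfg <- unet_config(n_levels = 1, base_channels = 3)
  p <- build_unet(cfg, seed = 1)
  expect_length(p$dec, 0)
  dims <- c(5, 6, 7)  # no divisibility constraint at one level
  out <- unet_forward(p, matrix(runif(prod(dims)), 1), dims)
  expect_equal(dim(out$output), c(2, prod(dims)))
})

test_that("softmax channels sum to one and grids must divide", {
  cfg <- unet_config(n_levels = 3, base_channels = 4)
  p <- build_unet(cfg, seed = 2)
  dims <- c(8, 8, 8)
  out <- unet_forward(p, matrix(rnorm(prod(dims)), 1), dims)$output
  expect_equal(colSums(out), rep(1, prod(dims)), tolerance = 1e-6)
  expect_error(unet_forward(p, matrix(0, 1, 6^3), c(6, 6, 6)),
               "divisible.*level", perl = TRUE)
})

test_that("analytic gradients match numerical differentiation", {
  for (mode in c("softmax_2ch", "sdt_1ch")) {
    dims <- c(8, 8, 8)
    cfg <- unet_config(n_levels = 2, base_channels = 3, output_mode = mode)
    par <- build_unet(cfg, seed = 5)
    set.seed(11)
    x <- matrix(runif(prod(dims)), nrow = 1)
    tgt2 <- pedistrip:::.mask_to_2ch(runif(prod(dims)) > 0.7)
    tgt_sdt <- rnorm(prod(dims))
    lossfun <- function(par, want_grads = FALSE) {
      fwd <- unet_forward(par, x, dims, cache = want_grads)
      if (mode == "softmax_2ch") {
        l <- dice_loss(tgt2, fwd$output)
        if (!want_grads) return(l)
        g <- pedistrip:::.dice_loss_grad(tgt2, fwd$output)
        p <- fwd$output
        gl <- p * (g - rep(colSums(g * p), each = 2))
      } else {
        l <- sdt_loss(tgt_sdt, fwd$output[1, ], 1e-3, 1, "wsdt")
        if (!want_grads) return(l)
        gl <- matrix(pedistrip:::.sdt_loss_grad(tgt_sdt, fwd$output[1, ],
                                                1e-3, 1, "wsdt"), 1)
      }
      list(loss = l, grads = pedistrip:::.unet_backward(par, fwd, gl))
    }
    ref <- lossfun(par, want_grads = TRUE)
    flat <- pedistrip:::.flatten_params(par)
    set.seed(13)
    for (nm in sample(names(flat), 6)) {
      i <- sample(length(flat[[nm]]), 1)
      eps <- 1e-6
      f2 <- flat; f2[[nm]][i] <- f2[[nm]][i] + eps
      lp <- lossfun(pedistrip:::.unflatten_params(par, f2))
      f2[[nm]][i] <- f2[[nm]][i] - 2 * eps
      lm_ <- lossfun(pedistrip:::.unflatten_params(par, f2))
      num <- (lp - lm_) / (2 * eps)
      expect_equal(ref$grads[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("prediction thresholds follow the stated conventions", {
  cfg <- unet_config(n_levels = 2, base_channels = 3)
  p <- build_unet(cfg, seed = 3)
  # force a constant all-brain output through the projection layer
  p$final$W[] <- 0
  p$final$b <- c(10, -10)
  img <- intensity_volume(array(runif(8^3), c(8, 8, 8)))
  m <- predict_mask(p, img)
  expect_true(all(vol_data(m) == 1L))
  st <- skull_strip(p, img)
  expect_equal(vol_data(st$stripped), vol_data(img))
  # all-background network zeroes the product
  p$final$b <- c(-10, 10)
  st0 <- skull_strip(p, img)
  expect_true(all(vol_data(st0$stripped) == 0))
  # support of the stripped image is inside the mask for any network
  p2 <- build_unet(cfg, seed = 9)
  st2 <- skull_strip(p2, img)
  expect_true(all(vol_data(st2$stripped)[vol_data(st2$mask) == 0L] == 0))
})

test_that("an SDT-mode network thresholds at zero, negative inside", {
  cfg <- unet_config(n_levels = 2, base_channels = 3, output_mode = "sdt_1ch")
  p <- build_unet(cfg, seed = 4)
  p$final$W[] <- 0
  p$final$b <- -1  # constant negative prediction = everything brain
  img <- intensity_volume(array(runif(8^3), c(8, 8, 8)))
  expect_true(all(vol_data(predict_mask(p, img)) == 1L))
  p$final$b <- 1
  expect_true(all(vol_data(predict_mask(p, img)) == 0L))
  # exact SDTs round-trip through the mask convention
  msk <- random_mask(10, seed = 2)
  bm <- brain_mask(array(as.integer(msk), dim(msk)))
  expect_identical(vol_data(sdt_to_mask(compute_sdt(bm))), vol_data(bm))
})

test_that("single-precision kernels agree with double to float tolerance", {
  dims <- c(8, 8, 8)
  for (mode in c("softmax_2ch", "sdt_1ch")) {
    cfg_d <- unet_config(n_levels = 2, base_channels = 4, output_mode = mode)
    cfg_s <- unet_config(n_levels = 2, base_channels = 4, output_mode = mode,
                         precision = "single")
    pd <- build_unet(cfg_d, seed = 21)
    ps <- build_unet(cfg_s, seed = 21)  # same draws, different kernels
    set.seed(3)
    x <- matrix(runif(prod(dims)), 1)
    od <- unet_forward(pd, x, dims)$output
    os <- unet_forward(ps, x, dims)$output
    expect_lt(max(abs(od - os)), 1e-4)
    # deterministic across calls
    os2 <- unet_forward(ps, x, dims)$output
    expect_identical(os, os2)
  }
})

test_that("checkpoints round-trip through disk", {
  cfg <- unet_config(n_levels = 2, base_channels = 3)
  p <- build_unet(cfg, seed = 6)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(list(params = p, note = "x"), path)
  ck <- load_checkpoint(path)
  expect_identical(pedistrip:::.flatten_params(ck$params),
                   pedistrip:::.flatten_params(p))
})
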