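small_map <- function(seed = 1, n = 24) {
  make_phantom_labelmap(phantom_spec(grid_size = n, seed = seed,
                                     csf_thickness_mm = 1,
                                     skull_thickness_mm = 1,
                                     scalp_thickness_mm = 1,
                                     shape_jitter = 0.3))
}

zero_config <- function() {
  synth_config(translation_range = 0, rotation_range = 0,
               scale_range = c(1, 1), shear_range = 0, warp_sd = 0,
               intensity_sd_range = c(0, 0), p_bias = 0, p_gamma = 0,
               p_crop = 0, p_downsample = 0, p_blur = 0)
}

test_that("config validation and YAML round trip", {
  expect_error(synth_config(scale_range = c(1.3, 0.7)), "well-ordered")
  expect_error(synth_config(p_bias = 1.5), "probability")
  expect_error(synth_config(downsample_factors = c(1, 2.5)), "integers")
  cfg <- synth_config(preset = "desk", seed = 17)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_synth_config(cfg, path)
  cfg2 <- read_synth_config(path)
  expect_equal(unclass(cfg2), unclass(cfg))
})

test_that("degenerate sampling ranges give the identity transform", {
  cfg <- zero_config()
  t <- sample_transform(cfg, dims = c(16, 16, 16), seed = 5)
  expect_equal(t$affine, diag(4), tolerance = 1e-12)
  expect_null(t$displacement)
  lm <- small_map()
  out <- apply_transform(lm, spatial_transform())
  expect_identical(vol_data(out), vol_data(lm))
})

test_that("affine parameters stay in range and center correctly", {
  cfg <- synth_config(rotation_range = 45)
  rots <- t(vapply(1:2000, function(s)
    attr(sample_transform(cfg, c(8, 8, 8), seed = s), "params")$rotation,
    numeric(3)))
  expect_true(all(abs(rots) <= 45))
  expect_gt(max(rots), 40)   # draws span the range
  expect_lt(min(rots), -40)
  se <- 45 / sqrt(3) / sqrt(length(rots))
  expect_lt(abs(mean(rots)), 3 * se)
})

test_that("pure integer translation shifts labels exactly", {
  lm <- small_map()
  aff <- diag(4); aff[1:3, 4] <- c(-3, 0, 0)  # sampling: src = v - 3 => shift +3
  out <- apply_transform(lm, spatial_transform(aff))
  d <- vol_data(lm)
  expect_identical(out$data[4:24, , ], d[1:21, , ])
  # counts conserved away from the border (the phantom has margin)
  expect_equal(sum(out$data == 1L), sum(d == 1L))
})

test_that("180-degree rotation is an involution on the interior", {
  lm <- small_map()
  cfg <- zero_config()
  aff <- pedistrip:::.build_affine(c(0, 0, 0), c(0, 0, 180), c(1, 1, 1),
                                   c(0, 0, 0), vol_dims(lm))
  t <- spatial_transform(aff)
  once <- apply_transform(lm, t)
  twice <- apply_transform(once, t)
  core <- 2:23
  expect_identical(twice$data[core, core, core],
                   vol_data(lm)[core, core, core])
})

test_that("sampled displacement fields are finite and optional", {
  cfg <- synth_config(preset = "desk")
  t <- sample_transform(cfg, c(16, 16, 16), seed = 2)
  expect_true(all(is.finite(t$displacement)))
  expect_equal(dim(t$displacement), c(3, 16^3))
  t0 <- sample_transform(synth_config(warp_sd = 0), c(16, 16, 16), seed = 2)
  expect_null(t0$displacement)
})

test_that("intensity synthesis draws honest per-label statistics", {
  lm <- small_map()
  cfg <- synth_config(intensity_sd_range = c(0, 0))
  img <- synthesize_intensities(lm, cfg, seed = 4)
  lab <- vol_data(lm)
  for (l in unique(as.vector(lab)))
    expect_equal(var(vol_data(img)[lab == l]), 0)

  # sample SD close to the drawn SD on a big label
  cfg2 <- synth_config(intensity_mean_range = c(100, 200),
                       intensity_sd_range = c(10, 10))
  big <- make_phantom_labelmap(phantom_spec(grid_size = 40, seed = 1,
                                            csf_thickness_mm = 1,
                                            skull_thickness_mm = 1.5,
                                            scalp_thickness_mm = 1.5,
                                            shape_jitter = 0.5))
  img2 <- synthesize_intensities(big, cfg2, seed = 8)
  lab2 <- vol_data(big)
  n_bg <- sum(lab2 == 0L)
  expect_gt(n_bg, 1e4)
  s_hat <- sd(vol_data(img2)[lab2 == 0L])
  expect_gt(s_hat, 9); expect_lt(s_hat, 11)

  # means are independent across labels over repeated draws
  cfg3 <- synth_config()
  draws <- t(vapply(1:300, function(s)
    attr(synthesize_intensities(lm, cfg3, seed = s), "draws")$means[c("1", "2")],
    numeric(2)))
  expect_lt(abs(cor(draws[, 1], draws[, 2])), 0.15)
})

test_that("corruptions compose in fixed order with honest degenerate cases", {
  lm <- small_map()
  cfg0 <- zero_config()
  img <- synthesize_intensities(lm, synth_config(intensity_sd_range = c(2, 2),
                                                 intensity_mean_range = c(20, 230)),
                                seed = 3)
  out <- corrupt(img, cfg0, seed = 1)
  mm <- (vol_data(img) - min(vol_data(img))) /
    (max(vol_data(img)) - min(vol_data(img)))
  expect_equal(vol_data(out), mm, tolerance = 1e-12)

  # injected bias field is recovered exactly from the log-ratio
  n <- vol_dims(lm)[1]
  ramp <- array(seq(-0.3, 0.3, length.out = n)[arrayInd(1:n^3, rep(n, 3))[, 2]],
                rep(n, 3))
  pos <- intensity_volume(vol_data(img) + 1, img$affine)
  biased <- apply_bias_field(pos, ramp)
  expect_equal(log(vol_data(biased) / vol_data(pos)), ramp, tolerance = 1e-6)
})

test_that("training pairs are deterministic, aligned, and well-behaved", {
  lm <- small_map()
  cfg <- synth_config(preset = "desk")
  p1 <- generate_training_pair(lm, cfg, step_seed = 9)
  p2 <- generate_training_pair(lm, cfg, step_seed = 9)
  expect_identical(vol_data(p1$image), vol_data(p2$image))
  expect_identical(vol_data(p1$labels), vol_data(p2$labels))
  expect_identical(attr(p1$image, "transform_hash"),
                   attr(p1$labels, "transform_hash"))

  # with zero-width ranges the pair is the normalized render plus input map
  p0 <- generate_training_pair(lm, zero_config(), step_seed = 2)
  expect_identical(vol_data(p0$labels), vol_data(lm))
  lab <- vol_data(p0$labels)
  for (l in unique(as.vector(lab)))
    expect_equal(var(vol_data(p0$image)[lab == l]), 0)

  # rendered image is grouped by the augmented labels: the uncorrupted
  # render's per-label variance matches the drawn global sd
  cfgv <- synth_config(preset = "desk", intensity_sd_range = c(6, 6),
                       p_bias = 0, p_gamma = 0, p_crop = 0,
                       p_downsample = 0, p_blur = 0)
  pv <- generate_training_pair(lm, cfgv, step_seed = 4)
  labv <- vol_data(pv$labels)
  # corrupt() min-max normalizes, so compare on the rescaled scale
  raw <- synthesize_intensities(pv$labels, cfgv,
                                seed = pedistrip:::.sub_seed(4, 42L))
  scale <- diff(range(vol_data(raw)))
  for (l in names(which(table(labv) > 3000))) {
    s_hat <- sd(vol_data(pv$image)[labv == as.integer(l)]) * scale
    expect_gt(s_hat, 4.5); expect_lt(s_hat, 7.5)
  }
})

test_that("sampled parameters cover their ranges and outputs stay finite", {
  lm <- small_map()
  cfg <- synth_config()  # full-scale ranges on purpose
  tr <- numeric(0); sc <- numeric(0)
  for (s in 1:200) {
    p <- attr(sample_transform(cfg, c(16, 16, 16), seed = s), "params")
    tr <- c(tr, p$translation); sc <- c(sc, p$scale)
  }
  expect_gt(diff(range(tr)) / (2 * cfg$translation_range), 0.9)
  expect_gt(diff(range(sc)) / diff(cfg$scale_range), 0.9)
  for (s in 1:100) {
    pr <- generate_training_pair(lm, cfg, step_seed = s)
    expect_true(all(is.finite(vol_data(pr$image))))
    expect_true(all(is.finite(vol_data(pr$labels))))
  }
})
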