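test_that("conforming an already-conformed volume is a fixed point", {
  n <- 20
  # LIA direction columns: i -> left, j -> inferior, k -> anterior
  aff <- matrix(c(-1, 0, 0, 0,  0, 0, -1, 0,  0, 1, 0, 0,  9.5, -9.5, 9.5, 1),
                4, 4)
  set.seed(1)
  img <- intensity_volume(array(rnorm(n^3), c(n, n, n)), aff)
  out <- conform(img, size = n, spacing_mm = 1, orientation = "LIA")
  expect_equal(vol_data(out), vol_data(img), tolerance = 1e-9)

  m <- random_mask(n, seed = 1)
  bm <- brain_mask(array(as.integer(m), dim(m)), aff)
  outm <- conform(bm, size = n, spacing_mm = 1, orientation = "LIA")
  expect_identical(vol_data(outm), vol_data(bm))  # labels: bit-exact
})

test_that("axis-permuted copies conform to identical arrays", {
  lm <- make_phantom_labelmap(phantom_spec(grid_size = 24, seed = 2,
                                           csf_thickness_mm = 1,
                                           skull_thickness_mm = 1,
                                           scalp_thickness_mm = 1,
                                           shape_jitter = 0.3))
  arr <- vol_data(lm)
  aff <- lm$affine
  # permuted storage: swap axes 1 and 2 in both the array and the affine
  perm <- aperm(arr, c(2, 1, 3))
  paff <- aff[, c(2, 1, 3, 4)]
  lmp <- label_map(perm, paff, lm$roles)
  c1 <- conform(lm, size = 32, spacing_mm = 1)
  c2 <- conform(lmp, size = 32, spacing_mm = 1)
  expect_identical(vol_data(c1), vol_data(c2))
})

test_that("label volumes are roughly conserved under resampled conforming", {
  spec <- phantom_spec(grid_size = 32, seed = 3, csf_thickness_mm = 1.2,
                       skull_thickness_mm = 1.2, scalp_thickness_mm = 1.2,
                       shape_jitter = 0.3)
  lm <- make_phantom_labelmap(spec)
  # 2x downsampled copy (2 mm voxels), then conformed back to 1 mm
  lm2 <- conform(lm, size = 16, spacing_mm = 2)
  back <- conform(lm2, size = 32, spacing_mm = 1)
  brain_ids <- lm$roles$label_id[lm$roles$role == "brain"]
  v0 <- sum(vol_data(lm) %in% brain_ids)
  v1 <- sum(vol_data(back) %in% brain_ids)
  expect_lt(abs(v1 - v0) / v0, 0.10)
})

test_that("conform validates orientation strings", {
  img <- intensity_volume(array(0, c(8, 8, 8)))
  expect_error(conform(img, size = 8, orientation = "XYZ"), "orientation")
  expect_error(conform(img, size = 8, orientation = "RRA"), "distinct")
})

test_that("dice metric matches hand counts and brute force", {
  n <- 12
  cube <- array(0L, c(n, n, n)); cube[4:5, 4:5, 4:5] <- 1L  # 8 voxels
  shifted <- array(0L, c(n, n, n)); shifted[5:6, 4:5, 4:5] <- 1L
  a <- brain_mask(cube); b <- brain_mask(shifted)
  expect_equal(dice_metric(a, a), 1.0)
  expect_equal(dice_metric(a, b), 0.5)  # 4 shared of 8+8
  disj <- array(0L, c(n, n, n)); disj[9:10, 9:10, 9:10] <- 1L
  expect_equal(dice_metric(a, brain_mask(disj)), 0.0)
  expect_equal(dice_metric(b, a), dice_metric(a, b))
  expect_error(dice_metric(a, brain_mask(array(0L, c(4, 4, 4)))), "grids")
  # both-empty convention
  e <- brain_mask(array(0L, c(n, n, n)))
  expect_equal(dice_metric(e, e), 1)
})

test_that("hausdorff distances match the all-pairs oracle", {
  a1 <- array(0L, c(9, 9, 9)); a1[3, 5, 5] <- 1L
  a2 <- array(0L, c(9, 9, 9)); a2[6, 5, 5] <- 1L
  expect_equal(hausdorff_metric(brain_mask(a1), brain_mask(a2)), 3.0)
  expect_equal(hausdorff_metric(brain_mask(a1), brain_mask(a1)), 0.0)
  for (s in 1:6) {
    ma <- random_mask(12, seed = s)
    mb <- random_mask(12, seed = s + 100)
    bma <- brain_mask(array(as.integer(ma), dim(ma)))
    bmb <- brain_mask(array(as.integer(mb), dim(mb)))
    expect_equal(hausdorff_metric(bma, bmb), brute_hausdorff(ma, mb),
                 tolerance = 1e-9)
    h95 <- hausdorff_metric(bma, bmb, percentile = 95)
    expect_lte(h95, hausdorff_metric(bma, bmb) + 1e-12)
    expect_equal(h95, brute_hausdorff(ma, mb, percentile = 95),
                 tolerance = 1e-9)
  }
  expect_error(hausdorff_metric(brain_mask(array(0L, c(4, 4, 4))),
                                brain_mask(array(1L, c(4, 4, 4)))), "empty")
})

test_that("hausdorff respects world coordinates under anisotropic spacing", {
  m1 <- random_mask(10, seed = 3)
  m2 <- random_mask(10, seed = 7)
  h1 <- hausdorff_metric(brain_mask(array(as.integer(m1), dim(m1))),
                         brain_mask(array(as.integer(m2), dim(m2))))
  aff2 <- diag(c(2, 2, 2, 1))
  h2 <- hausdorff_metric(brain_mask(array(as.integer(m1), dim(m1)), aff2),
                         brain_mask(array(as.integer(m2), dim(m2)), aff2))
  expect_equal(h2, 2 * h1, tolerance = 1e-12)
})

test_that("error maps average absolute disagreements", {
  n <- 8
  ref <- array(0L, c(n, n, n)); ref[3:6, 3:6, 3:6] <- 1L
  p1 <- ref; p1[1, 1, 1] <- 1L
  p2 <- ref; p2[8, 8, 8] <- 1L
  mk <- function(x) brain_mask(x)
  em <- error_map(list(list(predicted = mk(p1), reference = mk(ref)),
                       list(predicted = mk(p2), reference = mk(ref))))
  e <- vol_data(em)
  expect_equal(e[1, 1, 1], 0.5)
  expect_equal(e[8, 8, 8], 0.5)
  expect_equal(sum(e), 1.0)
  perfect <- error_map(list(list(predicted = mk(ref), reference = mk(ref))))
  expect_true(all(vol_data(perfect) == 0))
  single <- error_map(list(list(predicted = mk(p1), reference = mk(ref))))
  expect_equal(vol_data(single)[1, 1, 1], 1)
  expect_error(error_map(list(list(predicted = mk(ref),
                                   reference = brain_mask(array(0L, c(4, 4, 4)))))),
               "common grid")
})

test_that("cohort evaluation summarises per-case metrics", {
  n <- 10
  ref <- array(0L, c(n, n, n)); ref[3:7, 3:7, 3:7] <- 1L
  p <- ref; p[3, 3, 3] <- 0L
  rep_ <- evaluate_masks(list(case_a = list(predicted = brain_mask(p),
                                            reference = brain_mask(ref)),
                              case_b = list(predicted = brain_mask(ref),
                                            reference = brain_mask(ref))))
  expect_equal(nrow(rep_$per_case), 2)
  expect_equal(rep_$per_case$dice[2], 1)
  expect_true(all(rep_$per_case$hausdorff95_mm <= rep_$per_case$hausdorff_mm))
  expect_equal(rep_$summary$mean[rep_$summary$metric == "dice"],
               mean(rep_$per_case$dice))
})
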