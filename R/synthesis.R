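#' Configuration of the generative model
#'
#' Parameterizes the per-step synthesis of training images from label maps:
#' spatial augmentation (random affine composed with a smooth nonlinear warp),
#' per-label intensity sampling, and an ordered battery of corruptions (bias
#' field, gamma exponentiation, edge cropping, downsampling, Gaussian blur),
#' each firing with its own probability. Ranges deliberately exceed the
#' variability of acquired MRI so trained networks generalize across
#' contrasts and ages.
#'
#' The `"desk"` preset scales the millimeter-valued ranges to the small
#' phantom field of view used in examples and tests; the `"full"` preset is
#' sized for conformed 256 mm head volumes.
#'
#' @param preset `"full"` or `"desk"` baseline values; any argument given
#'   explicitly overrides the preset.
#' @param translation_range max |translation| per axis, mm.
#' @param rotation_range max |rotation| per axis, degrees.
#' @param scale_range per-axis scale factor interval.
#' @param shear_range max |shear| per axis pair.
#' @param warp_control_spacing control-point spacing of the nonlinear warp, mm.
#' @param warp_sd standard deviation of control-point displacements, mm.
#' @param intensity_mean_range interval for per-label mean intensities.
#' @param intensity_sd_range interval for the global voxel-noise SD.
#' @param bias_field_sd amplitude (SD of the log-field) of the bias field.
#' @param bias_control_spacing control-point spacing of the bias field, mm.
#' @param gamma_log_sd SD of the log exponent for intensity exponentiation.
#' @param crop_max_fraction max per-axis fraction zeroed from one edge.
#' @param downsample_factors admissible integer downsampling factors.
#' @param blur_sigma_range Gaussian blur sigma interval, mm.
#' @param p_bias,p_gamma,p_crop,p_downsample,p_blur firing probability of
#'   each corruption.
#' @param seed integer seed stored with the config.
#' @return A `synth_config` object.
#' @export
synth_config <- function(preset = c("full", "desk"),
                         translation_range = NULL, rotation_range = NULL,
                         scale_range = NULL, shear_range = NULL,
                         warp_control_spacing = NULL, warp_sd = NULL,
                         intensity_mean_range = NULL,
                         intensity_sd_range = NULL,
                         bias_field_sd = NULL, bias_control_spacing = NULL,
                         gamma_log_sd = NULL, crop_max_fraction = NULL,
                         downsample_factors = NULL, blur_sigma_range = NULL,
                         p_bias = NULL, p_gamma = NULL, p_crop = NULL,
                         p_downsample = NULL, p_blur = NULL, seed = 1L) {
  preset <- match.arg(preset)
  base <- list(
    translation_range = 15, rotation_range = 45, scale_range = c(0.7, 1.3),
    shear_range = 0.1, warp_control_spacing = 16, warp_sd = 3,
    intensity_mean_range = c(0, 255), intensity_sd_range = c(1, 15),
    bias_field_sd = 0.3, bias_control_spacing = 24, gamma_log_sd = 0.3,
    crop_max_fraction = 0.2, downsample_factors = c(1, 2, 4),
    blur_sigma_range = c(0.1, 2), p_bias = 0.9, p_gamma = 0.9, p_crop = 0.3,
    p_downsample = 0.5, p_blur = 0.9)
  if (preset == "desk") {
    base$translation_range <- 5
    base$warp_control_spacing <- 12
    base$warp_sd <- 1.5
    base$bias_control_spacing <- 16
    base$crop_max_fraction <- 0.15
    base$blur_sigma_range <- c(0.1, 1)
    base$downsample_factors <- c(1, 2)
  }
  supplied <- list(
    translation_range = translation_range, rotation_range = rotation_range,
    scale_range = scale_range, shear_range = shear_range,
    warp_control_spacing = warp_control_spacing, warp_sd = warp_sd,
    intensity_mean_range = intensity_mean_range,
    intensity_sd_range = intensity_sd_range, bias_field_sd = bias_field_sd,
    bias_control_spacing = bias_control_spacing, gamma_log_sd = gamma_log_sd,
    crop_max_fraction = crop_max_fraction,
    downsample_factors = downsample_factors,
    blur_sigma_range = blur_sigma_range, p_bias = p_bias, p_gamma = p_gamma,
    p_crop = p_crop, p_downsample = p_downsample, p_blur = p_blur)
  for (nm in names(supplied))
    if (!is.null(supplied[[nm]])) base[[nm]] <- supplied[[nm]]
  base$seed <- as.integer(seed)

  for (nm in c("scale_range", "intensity_mean_range", "intensity_sd_range",
               "blur_sigma_range"))
    if (length(base[[nm]]) != 2 || diff(base[[nm]]) < 0)
      stop(nm, " must be a well-ordered interval")
  for (nm in c("translation_range", "rotation_range", "shear_range",
               "warp_sd", "bias_field_sd", "gamma_log_sd"))
    if (base[[nm]] < 0) stop(nm, " must be >= 0")
  for (nm in c("p_bias", "p_gamma", "p_crop", "p_downsample", "p_blur"))
    if (base[[nm]] < 0 || base[[nm]] > 1)
      stop(nm, " must be a probability in [0, 1]")
  if (base$crop_max_fraction < 0 || base$crop_max_fraction >= 1)
    stop("crop_max_fraction must be in [0, 1)")
  if (any(base$downsample_factors < 1) ||
      any(base$downsample_factors != round(base$downsample_factors)))
    stop("downsample_factors must be positive integers")
  if (base$warp_control_spacing <= 0 || base$bias_control_spacing <= 0)
    stop("control spacings must be positive")
  structure(base, class = "synth_config")
}

#' Serialize a synthesis configuration as YAML
#'
#' @param config a [synth_config()].
#' @param path file path.
#' @return `read_synth_config()` returns the reconstructed config;
#'   round-tripping is lossless.
#' @export
write_synth_config <- function(config, path) {
  stopifnot(inherits(config, "synth_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_synth_config
#' @export
read_synth_config <- function(path) {
  v <- yaml::read_yaml(path)
  do.call(synth_config, c(list(preset = "full"), v))
}

# ---- spatial transforms ----------------------------------------------------

#' Construct a spatial transform
#'
#' A transform is stored in resampling form: for an output voxel index v
#' (0-based), the source voxel coordinate is `affine %*% v + displacement(v)`,
#' i.e. the smooth displacement is applied on top of the affine part
#' (nonlinear-after-affine composition). The identity transform maps every
#' index to itself.
#'
#' @param affine invertible 4x4 voxel-to-voxel sampling matrix.
#' @param displacement `NULL`, or a 3 x N matrix of per-voxel offsets in
#'   source voxel units.
#' @return A `spatial_transform`.
#' @export
spatial_transform <- function(affine = diag(4), displacement = NULL) {
  if (abs(det(affine[1:3, 1:3])) < 1e-12)
    stop("transform affine is not invertible")
  if (!is.null(displacement) && any(!is.finite(displacement)))
    stop("displacement field must be finite")
  structure(list(affine = affine, displacement = displacement),
            class = "spatial_transform")
}

# forward affine (voxel coords about the grid center): T C R Sh S C^-1;
# the sampling matrix is its inverse
.build_affine <- function(translation_vox, rotation_deg, scale, shear, dims) {
  rad <- rotation_deg * pi / 180
  rx <- diag(4); rx[2:3, 2:3] <- matrix(c(cos(rad[1]), sin(rad[1]),
                                          -sin(rad[1]), cos(rad[1])), 2)
  ry <- diag(4); ry[c(1, 3), c(1, 3)] <- matrix(c(cos(rad[2]), -sin(rad[2]),
                                                  sin(rad[2]), cos(rad[2])), 2)
  rz <- diag(4); rz[1:2, 1:2] <- matrix(c(cos(rad[3]), sin(rad[3]),
                                          -sin(rad[3]), cos(rad[3])), 2)
  sh <- diag(4); sh[1, 2] <- shear[1]; sh[1, 3] <- shear[2]; sh[2, 3] <- shear[3]
  sc <- diag(c(scale, 1))
  tr <- diag(4); tr[1:3, 4] <- translation_vox
  ce <- diag(4); ce[1:3, 4] <- (dims - 1) / 2
  ci <- diag(4); ci[1:3, 4] <- -(dims - 1) / 2
  fwd <- tr %*% ce %*% rz %*% ry %*% rx %*% sh %*% sc %*% ci
  solve(fwd)
}

#' Sample a random spatial transform
#'
#' Affine parameters (translation, rotation, per-axis scale, shear) are drawn
#' uniformly from their configured ranges; the nonlinear part draws Gaussian
#' per-axis offsets on a coarse control grid (spacing `warp_control_spacing`,
#' SD `warp_sd`, both mm) and upsamples them smoothly to the full grid.
#'
#' @param config a [synth_config()].
#' @param dims grid size (length-3 integer) the transform will act on.
#' @param spacing voxel spacing in mm.
#' @param seed integer seed.
#' @return A `spatial_transform`; the drawn parameters are attached as
#'   attribute `"params"`.
#' @export
sample_transform <- function(config, dims, spacing = c(1, 1, 1), seed = 1L) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(.sub_seed(seed, 11L))
  pars <- list(
    translation = runif(3, -config$translation_range, config$translation_range),
    rotation = runif(3, -config$rotation_range, config$rotation_range),
    scale = runif(3, config$scale_range[1], config$scale_range[2]),
    shear = runif(3, -config$shear_range, config$shear_range))
  aff <- .build_affine(pars$translation / spacing, pars$rotation, pars$scale,
                       pars$shear, dims)

  disp <- NULL
  if (config$warp_sd > 0) {
    set.seed(.sub_seed(seed, 12L))
    sp_vox <- config$warp_control_spacing / spacing
    comp <- lapply(1:3, function(a)
      as.vector(.smooth_field(dims, sp_vox, config$warp_sd)) / spacing[a])
    disp <- rbind(comp[[1]], comp[[2]], comp[[3]])
  }
  tr <- spatial_transform(aff, disp)
  attr(tr, "params") <- pars
  tr
}

.transform_hash <- function(t) {
  digest::digest(list(t$affine, t$displacement), algo = "xxhash64")
}

#' Resample a label map through a spatial transform
#'
#' Nearest-neighbor interpolation; voxels mapped outside the field of view
#' receive the background label 0. The label-role table is unchanged. The
#' transform's hash is attached as attribute `"transform_hash"` so paired
#' outputs can assert that they share a transform.
#'
#' @param labelmap a [label_map()].
#' @param t a `spatial_transform`.
#' @return The resampled [label_map()].
#' @export
apply_transform <- function(labelmap, t) {
  stopifnot(inherits(labelmap, "label_map"), inherits(t, "spatial_transform"))
  dims <- vol_dims(labelmap)
  out <- .resample3(array(as.double(labelmap$data), dims), dims,
                    as.integer(dims), t$affine, t$displacement, 0L, 0, FALSE)
  roles <- labelmap$roles
  if (!0L %in% roles$label_id)
    roles <- rbind(data.frame(label_id = 0L, name = "background",
                              role = "nonbrain", stringsAsFactors = FALSE),
                   roles)
  lm <- label_map(array(as.integer(round(out)), dims), labelmap$affine, roles)
  attr(lm, "transform_hash") <- .transform_hash(t)
  lm
}

# ---- intensity synthesis and corruption ------------------------------------

#' Render a gray-scale image from a label map
#'
#' Draws one mean intensity per label (uniform on `intensity_mean_range`) and
#' one global noise SD (uniform on `intensity_sd_range`), then samples each
#' voxel from a normal distribution around its label mean; clamped at 0.
#'
#' @param labelmap a [label_map()].
#' @param config a [synth_config()].
#' @param seed integer seed.
#' @return An [intensity_volume()]; the drawn parameters are attached as
#'   attribute `"draws"` (`means` named by label, `sd`).
#' @export
synthesize_intensities <- function(labelmap, config, seed = 1L) {
  stopifnot(inherits(labelmap, "label_map"), inherits(config, "synth_config"))
  lab <- labelmap$data
  ids <- sort(unique(as.vector(lab)))
  set.seed(.sub_seed(seed, 21L))
  means <- runif(length(ids), config$intensity_mean_range[1],
                 config$intensity_mean_range[2])
  names(means) <- ids
  sd0 <- runif(1, config$intensity_sd_range[1], config$intensity_sd_range[2])
  img <- array(means[match(lab, ids)], dim(lab))
  if (sd0 > 0) img <- img + array(rnorm(length(img), 0, sd0), dim(lab))
  img[img < 0] <- 0
  out <- intensity_volume(img, labelmap$affine)
  attr(out, "draws") <- list(means = means, sd = sd0)
  h <- attr(labelmap, "transform_hash")
  if (!is.null(h)) attr(out, "transform_hash") <- h
  out
}

#' Multiply an image by a smooth bias field
#'
#' @param image an [intensity_volume()].
#' @param log_field 3D array; the image is multiplied by `exp(log_field)`.
#' @return The biased [intensity_volume()].
#' @export
apply_bias_field <- function(image, log_field) {
  stopifnot(inherits(image, "intensity_volume"),
            all(dim(log_field) == vol_dims(image)))
  out <- image
  out$data <- image$data * exp(log_field)
  out
}

.minmax <- function(x) {
  r <- range(x)
  if (r[2] > r[1]) (x - r[1]) / (r[2] - r[1]) else x * 0
}

#' Apply randomized corruptions to a synthetic image
#'
#' In fixed order: (1) multiplicative bias field `exp(smooth field)`;
#' (2) min-max normalization to `[0, 1]` (always applied) followed, with
#' probability `p_gamma`, by voxelwise exponentiation with exponent
#' `exp(N(0, gamma_log_sd))`; (3) zeroing of a random edge slab per axis;
#' (4) block-downsampling by a random admissible factor with nearest
#' restoration to the original grid; (5) Gaussian blur. Each corruption fires
#' with its configured probability from its own derived random stream, so a
#' corruption's draws do not perturb the others'.
#'
#' @param image non-negative [intensity_volume()].
#' @param config a [synth_config()].
#' @param seed integer seed.
#' @return The corrupted [intensity_volume()] on the same grid, values in
#'   `[0, 1]` up to gamma/bias scaling.
#' @export
corrupt <- function(image, config, seed = 1L) {
  stopifnot(inherits(image, "intensity_volume"), inherits(config, "synth_config"))
  dims <- vol_dims(image)
  spacing <- voxel_spacing(image)
  img <- image$data

  set.seed(.sub_seed(seed, 30L))
  fire <- runif(5) < c(config$p_bias, config$p_gamma, config$p_crop,
                       config$p_downsample, config$p_blur)

  if (fire[1] && config$bias_field_sd > 0) {
    set.seed(.sub_seed(seed, 31L))
    logf <- .smooth_field(dims, config$bias_control_spacing / spacing,
                          config$bias_field_sd)
    img <- img * exp(logf)
  }
  img <- .minmax(img)
  if (fire[2] && config$gamma_log_sd > 0) {
    set.seed(.sub_seed(seed, 32L))
    img <- img^exp(rnorm(1, 0, config$gamma_log_sd))
  }
  if (fire[3] && config$crop_max_fraction > 0) {
    set.seed(.sub_seed(seed, 33L))
    for (a in 1:3) {
      nvox <- floor(runif(1, 0, config$crop_max_fraction) * dims[a])
      if (nvox < 1) next
      idx <- if (runif(1) < 0.5) seq_len(nvox) else dims[a] - seq_len(nvox) + 1
      if (a == 1) img[idx, , ] <- 0
      else if (a == 2) img[, idx, ] <- 0
      else img[, , idx] <- 0
    }
  }
  if (fire[4]) {
    set.seed(.sub_seed(seed, 34L))
    f <- config$downsample_factors[sample.int(length(config$downsample_factors), 1)]
    if (f > 1) img <- .block_down_up(img, as.integer(dims), as.integer(f))
  }
  if (fire[5]) {
    set.seed(.sub_seed(seed, 35L))
    sig_mm <- runif(1, config$blur_sigma_range[1], config$blur_sigma_range[2])
    img <- .gaussian_blur3(img, as.integer(dims), sig_mm / spacing)
  }
  out <- intensity_volume(array(img, dims), image$affine)
  h <- attr(image, "transform_hash")
  if (!is.null(h)) attr(out, "transform_hash") <- h
  out
}

#' Generate one synthetic training pair
#'
#' Draws a spatial transform, resamples the label map through it, renders the
#' synthetic image from the *augmented* labels (guaranteeing exact image/label
#' correspondence) and corrupts it. Deterministic given
#' `(labelmap, config, step_seed)`; image and label map carry the same
#' `"transform_hash"` attribute.
#'
#' @param labelmap a [label_map()] (typically a whole-head map).
#' @param config a [synth_config()].
#' @param step_seed integer seed for this step.
#' @return list with elements `image` ([intensity_volume()]) and `labels`
#'   (augmented [label_map()]).
#' @export
generate_training_pair <- function(labelmap, config, step_seed = 1L) {
  dims <- vol_dims(labelmap)
  t <- sample_transform(config, dims, voxel_spacing(labelmap),
                        seed = .sub_seed(step_seed, 41L))
  warped <- apply_transform(labelmap, t)
  img <- synthesize_intensities(warped, config, seed = .sub_seed(step_seed, 42L))
  img <- corrupt(img, config, seed = .sub_seed(step_seed, 43L))
  list(image = img, labels = warped)
}
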