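#' Specification for a synthetic head phantom
#'
#' The phantom generator produces head-like label maps with the nested
#' compartments the skull-stripping pipeline assumes: background containing a
#' scalp shell, containing a skull shell, containing an extracerebral CSF
#' shell, containing the brain, which is subdivided into up to six structures
#' (white matter, cortical gray matter, deep gray matter, ventricles,
#' cerebellum, brainstem). Geometry is superellipsoid-based with a smooth
#' seeded radial perturbation (`shape_jitter`, mm) so that derived masks are
#' non-convex enough to exercise morphological closing and hole filling.
#'
#' @param grid_size voxels per axis (cubic grid, >= 16).
#' @param voxel_size_mm isotropic voxel spacing.
#' @param seed integer seed; phantoms are pure functions of the spec.
#' @param n_brain_labels number of distinct brain labels, 1..6. Structures
#'   beyond the count are merged into white matter.
#' @param csf_thickness_mm,skull_thickness_mm,scalp_thickness_mm shell
#'   thicknesses in mm (>= 0).
#' @param shape_jitter amplitude of the smooth boundary perturbation in mm.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_size = 64, voxel_size_mm = 1.0, seed = 1L,
                         n_brain_labels = 6, csf_thickness_mm = 2,
                         skull_thickness_mm = 3, scalp_thickness_mm = 3,
                         shape_jitter = 1.5) {
  if (grid_size < 16) stop("grid_size must be >= 16")
  if (voxel_size_mm <= 0) stop("voxel_size_mm must be positive")
  if (any(c(csf_thickness_mm, skull_thickness_mm, scalp_thickness_mm) < 0))
    stop("shell thicknesses must be >= 0")
  if (shape_jitter < 0) stop("shape_jitter must be >= 0")
  if (!n_brain_labels %in% 1:6) stop("n_brain_labels must be in 1..6")
  structure(list(grid_size = as.integer(grid_size),
                 voxel_size_mm = voxel_size_mm, seed = as.integer(seed),
                 n_brain_labels = as.integer(n_brain_labels),
                 csf_thickness_mm = csf_thickness_mm,
                 skull_thickness_mm = skull_thickness_mm,
                 scalp_thickness_mm = scalp_thickness_mm,
                 shape_jitter = shape_jitter),
            class = "phantom_spec")
}

#' Desk-scale phantom specification
#'
#' A 48-voxel phantom with proportionally thinner extracerebral shells,
#' sized so the full train/evaluate loop runs at desk scale; used by the
#' package's worked examples.
#'
#' @param seed integer seed.
#' @param grid_size voxels per axis (default 48).
#' @return A [phantom_spec()].
#' @export
desk_phantom_spec <- function(seed = 1L, grid_size = 48) {
  phantom_spec(grid_size = grid_size, seed = seed, csf_thickness_mm = 1.5,
               skull_thickness_mm = 2, scalp_thickness_mm = 2,
               shape_jitter = 1)
}

#' Brain semi-axes (mm) implied by a phantom spec
#'
#' The brain compartment is a superellipsoid with semi-axes proportional to
#' the field of view; shells are added outward from these radii.
#'
#' @param spec a [phantom_spec()].
#' @return numeric length-3 vector of semi-axes in mm (x, y, z).
#' @export
phantom_brain_radii <- function(spec) {
  fov <- spec$grid_size * spec$voxel_size_mm
  c(0.28, 0.33, 0.26) * fov
}

# superellipsoid "radius fraction" (1 on the surface), exponent p
.superellipsoid_rho <- function(cx, cy, cz, radii, p = 2.5) {
  ((abs(cx) / radii[1])^p + (abs(cy) / radii[2])^p +
     (abs(cz) / radii[3])^p)^(1 / p)
}

# smooth random field: N(0, sd) on a coarse control grid, trilinearly
# upsampled to the full grid; control spacing in voxels
.smooth_field <- function(dims, spacing_vox, sd) {
  nc <- pmax(2L, as.integer(ceiling((dims - 1) / spacing_vox)) + 2L)
  coarse <- array(rnorm(prod(nc), 0, sd), nc)
  m <- diag(4)
  diag(m)[1:3] <- 1 / spacing_vox
  .resample3(coarse, dim(coarse), as.integer(dims), m, NULL, 1L, 0, TRUE)
}

.phantom_label_names <- c("white_matter", "cortical_gray", "deep_gray",
                          "ventricles", "cerebellum", "brainstem")

#' Generate a head-like label map
#'
#' @param spec a [phantom_spec()].
#' @return A [label_map()] with labels 0 (background), 1..6 (brain
#'   structures), 7 (extracerebral CSF, role `csf_nonvent`), 8 (skull) and
#'   9 (scalp); the role table marks ventricles as `brain` so ventricular CSF
#'   is part of the target mask while the sulcal/extracerebral CSF shell is
#'   not.
#' @export
make_phantom_labelmap <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$grid_size
  vox <- spec$voxel_size_mm
  fov <- n * vox

  r_brain <- phantom_brain_radii(spec)
  r_csf <- r_brain + spec$csf_thickness_mm
  r_skull <- r_csf + spec$skull_thickness_mm
  r_scalp <- r_skull + spec$scalp_thickness_mm

  # sizing: every shell must fit inside the grid with a half-voxel margin
  shells <- list(brain = r_brain, csf = r_csf, skull = r_skull,
                 scalp = r_scalp)
  for (nm in names(shells)) {
    if (max(shells[[nm]]) + spec$shape_jitter > fov / 2 - vox / 2)
      stop(sprintf("grid too small: the '%s' shell (max radius %.1f mm + jitter) does not fit a %.0f mm field of view",
                   nm, max(shells[[nm]]), fov))
  }

  cc <- (seq_len(n) - 1 - (n - 1) / 2) * vox
  cx <- array(rep(cc, times = n * n), c(n, n, n))
  cy <- array(rep(rep(cc, each = n), times = n), c(n, n, n))
  cz <- array(rep(cc, each = n * n), c(n, n, n))

  set.seed(.sub_seed(spec$seed, 1L))
  jitter <- if (spec$shape_jitter > 0)
    .smooth_field(c(n, n, n), rep(max(4, n / 8), 3), 1) *
      (spec$shape_jitter / mean(r_brain))
  else array(0, c(n, n, n))

  rho_b <- .superellipsoid_rho(cx, cy, cz, r_brain) + jitter
  lab <- array(0L, c(n, n, n))
  if (spec$scalp_thickness_mm > 0)
    lab[.superellipsoid_rho(cx, cy, cz, r_scalp) + jitter <= 1] <- 9L
  if (spec$skull_thickness_mm > 0)
    lab[.superellipsoid_rho(cx, cy, cz, r_skull) + jitter <= 1] <- 8L
  if (spec$csf_thickness_mm > 0)
    lab[.superellipsoid_rho(cx, cy, cz, r_csf) + jitter <= 1] <- 7L

  brain <- rho_b <= 1
  lab[brain] <- 1L  # white matter fallback for all brain voxels

  keep <- spec$n_brain_labels
  if (keep >= 2) lab[brain & rho_b > 0.78] <- 2L  # cortical gray rim
  if (keep >= 5) {  # posterior-inferior cerebellum wedge
    cereb <- brain & cy < -0.35 * r_brain[2] & cz < -0.15 * r_brain[3]
    lab[cereb] <- 5L
  }
  if (keep >= 6) {  # central inferior brainstem column
    rs <- pmax(0.14 * r_brain[c(1, 2)], 1.7 * vox)
    stem <- brain & sqrt((cx / rs[1])^2 + ((cy + 0.05 * r_brain[2]) / rs[2])^2) <= 1 &
      cz < -0.25 * r_brain[3]
    lab[stem] <- 6L
  }
  r_vent <- pmax(c(0.20, 0.30, 0.18) * r_brain * 0.55, 1.7 * vox)
  if (keep >= 3) {  # deep gray shell around the ventricles
    rho_v <- .superellipsoid_rho(cx, cy, cz, r_vent, p = 2)
    lab[brain & rho_v <= 1.9 & rho_v > 1] <- 3L
    if (keep >= 4) lab[brain & rho_v <= 1] <- 4L
  }

  roles <- data.frame(
    label_id = c(0L, seq_len(keep), 7L, 8L, 9L),
    name = c("background", .phantom_label_names[seq_len(keep)],
             "csf_extracerebral", "skull", "scalp"),
    role = c("nonbrain", rep("brain", keep),
             "csf_nonvent", "nonbrain", "nonbrain"),
    stringsAsFactors = FALSE)
  present <- sort(unique(as.vector(lab)))
  empty <- setdiff(roles$label_id, c(present, if (spec$csf_thickness_mm == 0) 7L,
                                     if (spec$skull_thickness_mm == 0) 8L,
                                     if (spec$scalp_thickness_mm == 0) 9L))
  if (length(empty))
    stop("phantom geometry left declared labels empty: ",
         paste(empty, collapse = ", "), " (increase grid_size)")
  roles <- roles[roles$label_id %in% present, , drop = FALSE]

  label_map(lab, .default_affine(c(n, n, n), rep(vox, 3)), roles)
}

# fixed per-label intensity means; t2-like inverts the gray/white ordering
.phantom_means <- list(
  t1_like = c(`0` = 5, `1` = 110, `2` = 70, `3` = 80, `4` = 30, `5` = 75,
              `6` = 90, `7` = 40, `8` = 30, `9` = 95),
  t2_like = c(`0` = 5, `1` = 60, `2` = 100, `3` = 90, `4` = 180, `5` = 95,
              `6` = 70, `7` = 160, `8` = 40, `9` = 80))

#' Render an acquired-like image from a phantom label map
#'
#' Assigns a fixed mean intensity per label (T2-like contrast inverts the
#' gray/white ordering relative to T1-like, as in structural MRI of the
#' developing brain) and adds Gaussian noise.
#'
#' @param labelmap a [label_map()].
#' @param contrast `"t1_like"` or `"t2_like"`.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param seed integer seed for the noise.
#' @return An [intensity_volume()] with the affine of `labelmap`.
#' @export
make_phantom_image <- function(labelmap, contrast = c("t1_like", "t2_like"),
                               noise_sd = 0, seed = 1L) {
  stopifnot(inherits(labelmap, "label_map"))
  contrast <- match.arg(contrast)
  means <- .phantom_means[[contrast]]
  lab <- labelmap$data
  ids <- sort(unique(as.vector(lab)))
  if (!all(as.character(ids) %in% names(means)))
    stop("phantom intensity table has no mean for labels: ",
         paste(setdiff(ids, as.integer(names(means))), collapse = ", "))
  img <- array(means[as.character(lab)], dim(lab))
  if (noise_sd > 0) {
    # unclamped so per-label sample means stay unbiased estimates of the
    # assigned means; callers needing non-negativity can clamp themselves
    set.seed(.sub_seed(seed, 2L))
    img <- img + array(rnorm(length(img), 0, noise_sd), dim(lab))
  }
  intensity_volume(img, labelmap$affine)
}
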