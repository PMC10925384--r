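.axis_vectors <- list(R = c(1, 0, 0), L = c(-1, 0, 0),
                      A = c(0, 1, 0), P = c(0, -1, 0),
                      S = c(0, 0, 1), I = c(0, 0, -1))

.orientation_matrix <- function(orientation) {
  letters3 <- strsplit(toupper(orientation), "")[[1]]
  if (length(letters3) != 3 || !all(letters3 %in% names(.axis_vectors)))
    stop("orientation must be three of R/L/A/P/S/I, e.g. 'LIA'")
  d <- vapply(letters3, function(l) .axis_vectors[[l]], numeric(3))
  if (abs(det(d)) < 0.5)
    stop("orientation letters must name three distinct axes")
  d
}

#' Conform a volume to a canonical grid
#'
#' Resamples onto a cubic grid of `size` voxels per axis at isotropic
#' `spacing_mm`, with the axes oriented per `orientation` (default LIA:
#' voxel axes increase to the subject's left, inferior, anterior) and the
#' field of view centered on the input's world-space center. Intensities are
#' interpolated trilinearly; label maps and masks use nearest-neighbor
#' (linear interpolation of integer labels is ill-defined).
#'
#' @param vol an [intensity_volume()], [label_map()] or [brain_mask()].
#' @param size voxels per axis of the conformed grid (default 256).
#' @param spacing_mm isotropic voxel size (default 1).
#' @param orientation three-letter axis code (default `"LIA"`).
#' @return The conformed volume, same class as the input.
#' @export
conform <- function(vol, size = 256, spacing_mm = 1.0, orientation = "LIA") {
  stopifnot(inherits(vol, "pd_volume"))
  a_in <- vol$affine
  d <- .orientation_matrix(orientation) * spacing_mm
  dims_in <- vol_dims(vol)
  center_world <- (a_in %*% c((dims_in - 1) / 2, 1))[1:3]
  a_out <- rbind(cbind(d, center_world - d %*% rep((size - 1) / 2, 3)),
                 c(0, 0, 0, 1))
  m <- solve(a_in) %*% a_out  # conformed voxel -> input voxel
  odims <- as.integer(rep(size, 3))
  is_labels <- inherits(vol, "label_map") || inherits(vol, "brain_mask")
  res <- .resample3(array(as.double(vol$data), dims_in), as.integer(dims_in),
                    odims, m, NULL, if (is_labels) 0L else 1L, 0, FALSE)
  if (inherits(vol, "label_map")) {
    roles <- vol$roles
    if (!0L %in% roles$label_id)
      roles <- rbind(data.frame(label_id = 0L, name = "background",
                                role = "nonbrain", stringsAsFactors = FALSE),
                     roles)
    label_map(array(as.integer(round(res)), odims), a_out, roles)
  } else if (inherits(vol, "brain_mask"))
    brain_mask(array(as.integer(round(res)), odims), a_out)
  else intensity_volume(array(res, odims), a_out)
}

.check_same_grid <- function(a, b) {
  if (!all(vol_dims(a) == vol_dims(b)))
    stop("masks are on different grids")
}

#' Volumetric Dice overlap of two masks
#'
#' `2|A intersect B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b [brain_mask()] objects on the same grid.
#' @return Dice fraction in `[0, 1]`.
#' @export
dice_metric <- function(a, b) {
  stopifnot(inherits(a, "brain_mask"), inherits(b, "brain_mask"))
  .check_same_grid(a, b)
  na <- sum(a$data)
  nb <- sum(b$data)
  if (na + nb == 0) return(1)
  2 * sum(a$data & b$data) / (na + nb)
}

.boundary_voxels <- function(mask_arr, dims) {
  m <- mask_arr != 0L
  interior <- .binary_morph(m, as.integer(dims), 0L, 1L, 6L, TRUE)
  m & !interior
}

#' Hausdorff distance between mask boundaries
#'
#' Boundaries are the mask voxels with an in-grid background face-neighbor;
#' directed
#' distances are measured between boundary voxel centers in world
#' millimeters. `percentile = 100` gives the classical Hausdorff distance
#' (max over both directions); `percentile = 95` the robust variant (max of
#' the two directed 95th percentiles).
#'
#' @param a,b nonempty [brain_mask()] objects on the same grid.
#' @param percentile 100 (default) or any percentile in (0, 100].
#' @return distance in mm.
#' @export
hausdorff_metric <- function(a, b, percentile = 100) {
  stopifnot(inherits(a, "brain_mask"), inherits(b, "brain_mask"))
  .check_same_grid(a, b)
  if (sum(a$data) == 0 || sum(b$data) == 0)
    stop("Hausdorff distance undefined for an empty mask")
  if (percentile <= 0 || percentile > 100)
    stop("percentile must be in (0, 100]")
  dims <- vol_dims(a)
  sp <- voxel_spacing(a)
  ba <- .boundary_voxels(a$data, dims)
  bb <- .boundary_voxels(b$data, dims)
  da <- .edt3(array(as.integer(ba), dims), as.integer(dims), sp)  # dist to dA
  db <- .edt3(array(as.integer(bb), dims), as.integer(dims), sp)
  dir_ab <- db[ba]  # for each boundary voxel of A, distance to dB
  dir_ba <- da[bb]
  stat <- function(x) if (percentile == 100) max(x) else
    unname(quantile(x, percentile / 100, type = 7))
  max(stat(dir_ab), stat(dir_ba))
}

#' Voxelwise error proportion across a cohort
#'
#' Mean of `|predicted - reference|` over cases, all masks on one shared
#' grid; a value of 0.4 at a voxel means 40% of cases misclassify it.
#'
#' @param cases list of cases, each a list with `predicted` and `reference`
#'   [brain_mask()] objects.
#' @return An [intensity_volume()] of error proportions in `[0, 1]`.
#' @export
error_map <- function(cases) {
  stopifnot(length(cases) >= 1)
  dims <- vol_dims(cases[[1]]$predicted)
  acc <- array(0, dims)
  for (cs in cases) {
    stopifnot(inherits(cs$predicted, "brain_mask"),
              inherits(cs$reference, "brain_mask"))
    if (!all(vol_dims(cs$predicted) == dims) ||
        !all(vol_dims(cs$reference) == dims))
      stop("all masks must share one common grid")
    acc <- acc + abs(cs$predicted$data - cs$reference$data)
  }
  intensity_volume(acc / length(cases), cases[[1]]$predicted$affine)
}

#' Cohort mask-accuracy report
#'
#' @param cases list of cases as in [error_map()], optionally named.
#' @param percentile robust Hausdorff percentile reported alongside the max.
#' @return list with `per_case` (data frame: case, dice, hausdorff_mm,
#'   hausdorff95_mm) and `summary` (mean/sd per metric).
#' @export
evaluate_masks <- function(cases, percentile = 95) {
  per <- do.call(rbind, lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    data.frame(
      case = if (!is.null(names(cases))) names(cases)[i] else paste0("case", i),
      dice = dice_metric(cs$predicted, cs$reference),
      hausdorff_mm = hausdorff_metric(cs$predicted, cs$reference, 100),
      hausdorff95_mm = hausdorff_metric(cs$predicted, cs$reference,
                                        percentile),
      stringsAsFactors = FALSE)
  }))
  summ <- data.frame(
    metric = c("dice", "hausdorff_mm", "hausdorff95_mm"),
    mean = c(mean(per$dice), mean(per$hausdorff_mm), mean(per$hausdorff95_mm)),
    sd = c(sd(per$dice), sd(per$hausdorff_mm), sd(per$hausdorff95_mm)))
  list(per_case = per, summary = summ)
}
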