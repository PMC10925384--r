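#' Derive the ground-truth brain mask from a label map
#'
#' Three stages, mirroring how training targets are built from whole-head
#' label maps: (1) merge all labels with role `brain` (ventricles count as
#' brain; the extracerebral/sulcal CSF label, role `csf_nonvent`, is
#' excluded) into a binary map; (2) bridge the space between brain folds by
#' morphological closing — `iterations` dilations followed by the same number
#' of erosions with a face-neighbor (6-connected) structuring element;
#' (3) fill any remaining 3D holes (background components not connected to
#' the volume border become mask).
#'
#' @param labelmap a [label_map()] with a role table.
#' @param iterations closing iterations (default 10).
#' @param connectivity 6 (face neighbors, default) or 26.
#' @return A [brain_mask()].
#' @export
derive_brain_mask <- function(labelmap, iterations = 10, connectivity = 6) {
  stopifnot(inherits(labelmap, "label_map"))
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26")
  brain_ids <- labelmap$roles$label_id[labelmap$roles$role == "brain"]
  if (!length(brain_ids))
    stop("empty target: the role table declares no brain labels")
  dims <- vol_dims(labelmap)
  raw <- array(labelmap$data %in% brain_ids, dims)
  closed <- raw
  if (iterations > 0) {
    # pad by iterations + 1 so the closing behaves as on an unbounded
    # domain: dilation clipped at the volume border would otherwise erode
    # back too far (or, on small grids, swallow the whole field of view)
    pad <- as.integer(iterations + 1)
    pdims <- as.integer(dims + 2L * pad)
    pm <- array(FALSE, pdims)
    pm[pad + seq_len(dims[1]), pad + seq_len(dims[2]),
       pad + seq_len(dims[3])] <- raw
    pm <- .binary_morph(pm, pdims, 1L, as.integer(iterations),
                        as.integer(connectivity))
    pm <- .binary_morph(pm, pdims, 0L, as.integer(iterations),
                        as.integer(connectivity))
    closed <- pm[pad + seq_len(dims[1]), pad + seq_len(dims[2]),
                 pad + seq_len(dims[3])]
  }
  filled <- fill_holes_3d(closed)
  brain_mask(array(as.integer(filled), dims), labelmap$affine)
}

#' Fill enclosed 3D holes in a binary volume
#'
#' Background voxels (6-connectivity) not reachable from the volume border
#' are switched to foreground.
#'
#' @param mask logical or 0/1 3D array.
#' @return logical 3D array.
#' @export
fill_holes_3d <- function(mask) {
  dims <- dim(mask)
  m <- array(as.logical(mask), dims)
  outside <- .outside_background(m, as.integer(dims))
  m | !outside
}

#' Signed Euclidean distance transform of a brain mask
#'
#' The boundary is the set of mask voxels with at least one in-grid
#' background face-neighbor. Distances are
#' measured center-to-center in world millimeters; the sign convention is
#' negative inside the mask and positive outside, so boundary voxels carry
#' distance 0 and the mask is recovered exactly by `sdt <= 0`
#' ([sdt_to_mask()]). Continuous network predictions are thresholded at
#' `< 0` instead.
#'
#' @param mask a [brain_mask()] containing both foreground and background.
#' @return A [distance_map()].
#' @export
compute_sdt <- function(mask) {
  stopifnot(inherits(mask, "brain_mask"))
  dims <- vol_dims(mask)
  m <- mask$data != 0L
  if (all(m) || !any(m))
    stop("degenerate mask: needs both foreground and background for an SDT")
  interior <- .binary_morph(m, as.integer(dims), 0L, 1L, 6L, TRUE)
  boundary <- m & !interior
  d <- .edt3(array(as.integer(boundary), dims), as.integer(dims),
             voxel_spacing(mask))
  sdt <- ifelse(m, -d, d)
  distance_map(array(sdt, dims), mask$affine)
}

#' Threshold a signed distance map back to a mask
#'
#' @param sdt a [distance_map()] following the negative-inside convention.
#' @param strict use `< 0` (for continuous predictions) instead of the exact
#'   `<= 0` recovery rule.
#' @return A [brain_mask()].
#' @export
sdt_to_mask <- function(sdt, strict = FALSE) {
  stopifnot(inherits(sdt, "distance_map"))
  m <- if (strict) sdt$data < 0 else sdt$data <= 0
  brain_mask(array(as.integer(m), vol_dims(sdt)), sdt$affine)
}

#' Derive both training targets from a label map
#'
#' @param labelmap a [label_map()].
#' @param iterations,connectivity passed to [derive_brain_mask()].
#' @return list with `mask` ([brain_mask()]) and `sdt` ([distance_map()]).
#' @export
derive_targets <- function(labelmap, iterations = 10, connectivity = 6) {
  mask <- derive_brain_mask(labelmap, iterations, connectivity)
  list(mask = mask, sdt = compute_sdt(mask))
}
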