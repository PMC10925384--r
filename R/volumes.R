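#' Volumetric containers
#'
#' `pedistrip` represents head volumes as light S3 objects holding a 3D array
#' and a 4x4 voxel-to-world (RAS) affine:
#'
#' * `intensity_volume()` — gray-scale head image (numeric array),
#' * `label_map()` — integer anatomical labels plus a label-role table with
#'   columns `label_id`, `name` and `role` in `brain`, `csf_nonvent`,
#'   `nonbrain`; the role table drives ground-truth mask derivation,
#' * `brain_mask()` — binary brain segmentation,
#' * `distance_map()` — signed Euclidean distance (mm) to the brain boundary,
#'   negative inside the mask.
#'
#' @param data 3D array (numeric for images/distances, integer-valued for
#'   labels, logical/0-1 for masks).
#' @param affine 4x4 voxel-to-world matrix (RAS convention, 0-based voxel
#'   indices).
#' @param roles data frame with columns `label_id`, `name`, `role`.
#' @return An object of the corresponding class.
#' @name volumes
NULL

.check_affine <- function(affine) {
  if (!is.matrix(affine) || !all(dim(affine) == c(4, 4)) ||
      any(!is.finite(affine)) || abs(det(affine[1:3, 1:3])) < 1e-12)
    stop("affine must be a finite, invertible 4x4 voxel-to-world matrix")
  affine
}

.default_affine <- function(dims, spacing = c(1, 1, 1)) {
  a <- diag(4)
  diag(a)[1:3] <- spacing
  a[1:3, 4] <- -(dims - 1) / 2 * spacing
  a
}

#' @rdname volumes
#' @export
intensity_volume <- function(data, affine = .default_affine(dim(data))) {
  stopifnot(length(dim(data)) == 3)
  structure(list(data = data, affine = .check_affine(affine)),
            class = c("intensity_volume", "pd_volume"))
}

.valid_roles <- c("brain", "csf_nonvent", "nonbrain")

#' @rdname volumes
#' @export
label_map <- function(data, affine = .default_affine(dim(data)), roles) {
  stopifnot(length(dim(data)) == 3)
  if (missing(roles) || !is.data.frame(roles) ||
      !all(c("label_id", "name", "role") %in% names(roles)))
    stop("label_map needs a roles data frame with columns label_id, name, role")
  if (!all(roles$role %in% .valid_roles))
    stop("label roles must be one of: ", paste(.valid_roles, collapse = ", "))
  if (anyDuplicated(roles$label_id))
    stop("duplicated label_id in role table")
  present <- sort(unique(as.vector(data)))
  missing_ids <- setdiff(present, roles$label_id)
  if (length(missing_ids))
    stop("labels present in volume but absent from role table: ",
         paste(missing_ids, collapse = ", "))
  storage.mode(data) <- "integer"
  structure(list(data = data, affine = .check_affine(affine),
                 roles = roles[order(roles$label_id), , drop = FALSE]),
            class = c("label_map", "pd_volume"))
}

#' @rdname volumes
#' @export
brain_mask <- function(data, affine = .default_affine(dim(data))) {
  stopifnot(length(dim(data)) == 3)
  if (is.logical(data)) {
    d <- dim(data)
    data <- array(as.integer(data), d)
  }
  if (!all(data %in% c(0L, 1L))) stop("brain mask values must be 0/1")
  storage.mode(data) <- "integer"
  structure(list(data = data, affine = .check_affine(affine)),
            class = c("brain_mask", "pd_volume"))
}

#' @rdname volumes
#' @export
distance_map <- function(data, affine = .default_affine(dim(data))) {
  stopifnot(length(dim(data)) == 3, is.numeric(data))
  structure(list(data = data, affine = .check_affine(affine)),
            class = c("distance_map", "pd_volume"))
}

#' Accessors for volumetric objects
#'
#' @param x a `pd_volume` object.
#' @return `vol_data()` the 3D array, `vol_affine()` the 4x4 matrix,
#'   `vol_dims()` the grid size, `voxel_spacing()` the per-axis spacing in mm.
#' @export
vol_data <- function(x) x$data

#' @rdname vol_data
#' @export
vol_affine <- function(x) x$affine

#' @rdname vol_data
#' @export
vol_dims <- function(x) dim(x$data)

#' @rdname vol_data
#' @export
voxel_spacing <- function(x) sqrt(colSums(x$affine[1:3, 1:3]^2))

#' @export
print.pd_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm\n", class(x)[1],
              paste(vol_dims(x), collapse = "x"),
              paste(signif(voxel_spacing(x), 3), collapse = "x")))
  if (!is.null(x$roles)) {
    cat("labels:\n")
    print(x$roles, row.names = FALSE)
  }
  invisible(x)
}

# ---- NIfTI input/output ----------------------------------------------------

.roles_sidecar <- function(path) {
  base <- sub("\\.nii(\\.gz)?$", "", path)
  paste0(base, ".labels.tsv")
}

#' Read and write volumes as NIfTI-1
#'
#' Images and distance maps are written with floating-point data, label maps
#' and masks with integer data. Label maps carry their label-role table in a
#' tab-separated sidecar file (`<stem>.labels.tsv` with columns `label_id`,
#' `name`, `role`) next to the NIfTI file.
#'
#' @param x volume object to write.
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param roles_path path of the sidecar role table; defaults to
#'   `<stem>.labels.tsv`.
#' @return `read_*` return the corresponding object; `write_volume` returns
#'   `path` invisibly.
#' @export
write_volume <- function(x, path, roles_path = .roles_sidecar(path)) {
  dat <- x$data
  datatype <- if (inherits(x, "label_map") || inherits(x, "brain_mask"))
    "int32" else "double"
  img <- RNifti::asNifti(dat, datatype = datatype)
  RNifti::sform(img) <- structure(x$affine, code = 2L)
  RNifti::writeNifti(img, path)
  if (inherits(x, "label_map"))
    write.table(x$roles, roles_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(path)
}

.read_nifti_array <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  list(data = array(as.vector(img), dim(img)[1:3]), affine = aff)
}

#' @rdname write_volume
#' @export
read_intensity_volume <- function(path) {
  r <- .read_nifti_array(path)
  intensity_volume(r$data, r$affine)
}

#' @rdname write_volume
#' @export
read_label_map <- function(path, roles_path = .roles_sidecar(path)) {
  r <- .read_nifti_array(path)
  if (!file.exists(roles_path))
    stop("label-role sidecar not found: ", roles_path)
  roles <- read.delim(roles_path, stringsAsFactors = FALSE)
  label_map(r$data, r$affine, roles)
}

#' @rdname write_volume
#' @export
read_brain_mask <- function(path) {
  r <- .read_nifti_array(path)
  brain_mask(array(as.integer(r$data != 0), dim(r$data)), r$affine)
}
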