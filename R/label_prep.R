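#' Polynomial non-uniformity correction
#'
#' Estimates a smooth multiplicative intensity bias as a low-order 3D
#' polynomial fitted to log-intensity over nonzero voxels, and divides it
#' out. The corrected image is rescaled so its mean over nonzero voxels
#' equals that of the input; zero (background) voxels are preserved exactly.
#' Intended to balance the intensity distribution before the non-brain GMM
#' fit, not as a full MRI inhomogeneity pipeline.
#'
#' @param image an [intensity_volume()], strictly positive where nonzero.
#' @param field_order total polynomial degree of the bias model (default 2).
#' @param max_fit_voxels cap on the number of voxels entering the fit; the
#'   fit subsamples deterministically (even stride) above it.
#' @return list with elements `corrected` (an [intensity_volume()]) and
#'   `field` (3D array; estimated multiplicative bias, 1 where background).
#' @export
correct_nonuniformity <- function(image, field_order = 2,
                                  max_fit_voxels = 200000L) {
  stopifnot(inherits(image, "intensity_volume"))
  dat <- image$data
  nz <- which(dat > 0)
  if (!length(nz)) stop("degenerate input: image has no positive voxels")
  if (any(dat < 0)) stop("image must be non-negative for log-domain fitting")

  dims <- dim(dat)
  idx <- nz
  if (length(idx) > max_fit_voxels)
    idx <- idx[seq(1, length(idx), length.out = max_fit_voxels)]
  coord <- arrayInd(idx, dims)
  # normalized coordinates in [-1, 1]
  u <- sweep(sweep(coord, 2, (dims + 1) / 2), 2, (dims - 1) / 2, "/")

  basis <- function(u) {
    cols <- list(rep(1, nrow(u)))
    for (i in 0:field_order)
      for (j in 0:(field_order - i))
        for (k in 0:(field_order - i - j))
          if (i + j + k > 0)
            cols[[length(cols) + 1L]] <- u[, 1]^i * u[, 2]^j * u[, 3]^k
    do.call(cbind, cols)
  }
  X <- basis(u)
  beta <- qr.coef(qr(X), log(dat[idx]))
  beta[is.na(beta)] <- 0

  coord_all <- arrayInd(nz, dims)
  u_all <- sweep(sweep(coord_all, 2, (dims + 1) / 2), 2, (dims - 1) / 2, "/")
  logf <- drop(basis(u_all) %*% beta)
  logf <- logf - mean(logf)  # unit-geometric-mean field
  field <- array(1, dims)
  field[nz] <- exp(logf)

  out <- dat
  out[nz] <- dat[nz] / field[nz]
  out[nz] <- out[nz] * (mean(dat[nz]) / mean(out[nz]))
  list(corrected = intensity_volume(out, image$affine), field = field)
}

#' Seeded 1-D Gaussian mixture fit to non-brain intensities
#'
#' Fits `n_components` Gaussians to the intensities of voxels outside the
#' brain mask by expectation-maximization, with k-means++-style seeded
#' initialization and a variance floor. Components are canonicalized by
#' ascending mean (the pseudo-labels carry no anatomical meaning, so the
#' ordering is purely for reproducibility); hard per-voxel assignments take
#' the maximum-responsibility component, ties broken by lowest index.
#'
#' @param image an [intensity_volume()].
#' @param brainmask a [brain_mask()] on the same grid; the fit uses voxels
#'   outside it.
#' @param n_components number of mixture components (default 6).
#' @param seed integer seed controlling initialization.
#' @param max_iter,tol EM stopping controls.
#' @return A `gmm_fit` object: means, variances, weights (summing to 1),
#'   per-voxel `assignment` array (component 1..k outside the mask, NA
#'   inside), and the per-iteration `loglik` trace (non-decreasing).
#' @export
fit_gmm_nonbrain <- function(image, brainmask, n_components = 6, seed = 1L,
                             max_iter = 300L, tol = 1e-8) {
  stopifnot(inherits(image, "intensity_volume"),
            inherits(brainmask, "brain_mask"))
  if (!all(vol_dims(image) == vol_dims(brainmask)))
    stop("image and brain mask grids differ")
  outside <- brainmask$data == 0L
  x <- as.vector(image$data[outside])
  k <- as.integer(n_components)
  if (length(unique(x)) < k)
    stop(sprintf(
      "only %d distinct intensity values outside the brain mask; reduce n_components below %d",
      length(unique(x)), k))

  set.seed(.sub_seed(seed, 3L))
  xs <- if (length(x) > 20000L) x[sample.int(length(x), 20000L)] else x
  # k-means++ init on the (sub)sample
  centers <- numeric(k)
  centers[1] <- xs[sample.int(length(xs), 1L)]
  if (k > 1) for (j in 2:k) {
    d2 <- vapply(xs, function(v) min((v - centers[1:(j - 1)])^2), numeric(1))
    centers[j] <- if (sum(d2) > 0)
      xs[sample.int(length(xs), 1L, prob = d2)] else xs[sample.int(length(xs), 1L)]
  }
  mu <- sort(centers)
  vfloor <- 1e-6 * stats::var(x) + 1e-12
  sig2 <- rep(max(stats::var(x) / k, vfloor), k)
  w <- rep(1 / k, k)

  loglik <- numeric(0)
  for (it in seq_len(max_iter)) {
    # E step in log space for stability
    lp <- vapply(1:k, function(j)
      log(w[j]) + stats::dnorm(x, mu[j], sqrt(sig2[j]), log = TRUE),
      numeric(length(x)))
    m <- apply(lp, 1, max)
    lse <- m + log(rowSums(exp(lp - m)))
    loglik <- c(loglik, sum(lse))
    r <- exp(lp - lse)
    # M step
    nk <- colSums(r)
    w <- nk / length(x)
    mu <- colSums(r * x) / nk
    sig2 <- pmax(colSums(r * outer(x, mu, "-")^2) / nk, vfloor)
    if (it > 1 && abs(loglik[it] - loglik[it - 1]) <
        tol * (abs(loglik[it]) + 1)) break
  }
  ord <- order(mu)
  mu <- mu[ord]; sig2 <- sig2[ord]; w <- w[ord]

  lp <- vapply(1:k, function(j)
    log(w[j]) + stats::dnorm(x, mu[j], sqrt(sig2[j]), log = TRUE),
    numeric(length(x)))
  hard <- max.col(lp, ties.method = "first")
  assignment <- array(NA_integer_, vol_dims(image))
  assignment[outside] <- hard

  structure(list(n_components = k, means = mu, variances = sig2, weights = w,
                 assignment = assignment, loglik = loglik, seed = seed),
            class = "gmm_fit")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("<gmm_fit> %d components, %d EM iterations\n",
              x$n_components, length(x$loglik)))
  print(data.frame(mean = x$means, sd = sqrt(x$variances),
                   weight = x$weights), row.names = FALSE)
  invisible(x)
}

#' Splice manual brain labels with non-brain GMM pseudo-labels
#'
#' Builds a whole-head training label map: voxels inside the brain mask keep
#' the manual labels; voxels outside receive the GMM component id offset into
#' a disjoint integer range and marked with role `nonbrain`. The result
#' records per-voxel provenance (`manual` or `gmm`).
#'
#' @param manual a [label_map()] of manual brain labels (with roles).
#' @param gmm a `gmm_fit` from [fit_gmm_nonbrain()] computed with the same
#'   mask.
#' @param brainmask the [brain_mask()] separating manual from GMM territory.
#' @param gmm_offset first integer id for GMM labels; defaults to
#'   `max(manual ids) + 1`. Supplying an id range that collides with manual
#'   labels is an error.
#' @return A `wholehead_label_map` (a [label_map()] with a `provenance`
#'   element: integer array, 1 = manual, 2 = gmm).
#' @export
splice_labels <- function(manual, gmm, brainmask, gmm_offset = NULL) {
  stopifnot(inherits(manual, "label_map"), inherits(gmm, "gmm_fit"),
            inherits(brainmask, "brain_mask"))
  if (!all(vol_dims(manual) == vol_dims(brainmask)))
    stop("manual labels and brain mask grids differ")
  ids <- manual$roles$label_id
  if (is.null(gmm_offset)) gmm_offset <- max(ids) + 1L
  gmm_ids <- gmm_offset + seq_len(gmm$n_components) - 1L
  clash <- intersect(gmm_ids, ids)
  if (length(clash))
    stop("GMM label ids collide with manual label ids: ",
         paste(clash, collapse = ", "), "; remap with a larger gmm_offset")

  inside <- brainmask$data != 0L
  out <- array(0L, vol_dims(manual))
  out[inside] <- manual$data[inside]
  gmm_lab <- gmm$assignment
  if (anyNA(gmm_lab[!inside]))
    stop("GMM assignment does not cover all non-brain voxels; refit with the same mask")
  out[!inside] <- gmm_offset - 1L + gmm_lab[!inside]

  provenance <- array(2L, vol_dims(manual))
  provenance[inside] <- 1L

  roles <- rbind(manual$roles,
                 data.frame(label_id = gmm_ids,
                            name = paste0("gmm_", seq_along(gmm_ids)),
                            role = "nonbrain", stringsAsFactors = FALSE))
  roles <- roles[roles$label_id %in% unique(as.vector(out)), , drop = FALSE]
  lm <- label_map(out, manual$affine, roles)
  lm$provenance <- provenance
  class(lm) <- c("wholehead_label_map", class(lm))
  lm
}

#' One-call whole-head label preparation
#'
#' Non-uniformity-corrects the head image, fits the non-brain GMM and splices
#' the pseudo-labels with the manual brain labels.
#'
#' @param image head [intensity_volume()].
#' @param manual manual brain [label_map()].
#' @param brainmask optional [brain_mask()]; defaults to `manual != 0`.
#' @param n_components,seed,field_order passed through.
#' @return A `wholehead_label_map`.
#' @export
prep_wholehead_labels <- function(image, manual, brainmask = NULL,
                                  n_components = 6, seed = 1L,
                                  field_order = 2) {
  if (is.null(brainmask))
    brainmask <- brain_mask(array(as.integer(manual$data != 0L),
                                  vol_dims(manual)), manual$affine)
  corr <- correct_nonuniformity(image, field_order = field_order)$corrected
  gmm <- fit_gmm_nonbrain(corr, brainmask, n_components = n_components,
                          seed = seed)
  splice_labels(manual, gmm, brainmask)
}
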