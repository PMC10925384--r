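#' Soft Dice loss over the two output channels
#'
#' For channels c in {brain, background}, the soft Dice is
#' \deqn{D_c = \frac{2 \sum_v y_c \hat y_c + \epsilon}{\sum_v y_c^2 + \sum_v \hat y_c^2 + \epsilon}}
#' summing over all voxels, with smoothing `eps` in numerator and
#' denominator; the loss is `-(D_brain + D_background) / 2`, ranging from -1
#' (perfect overlap) to 0 (disjoint supports).
#'
#' @param target 2 x N one-hot matrix (row 1 brain, row 2 background).
#' @param pred 2 x N prediction (softmax probabilities).
#' @param eps smoothing constant.
#' @return scalar loss.
#' @export
dice_loss <- function(target, pred, eps = 1e-6) {
  .check_2ch(target, pred)
  d <- .dice_channels(target, pred, eps)
  -mean(d)
}

.check_2ch <- function(target, pred) {
  if (!is.matrix(target) || !is.matrix(pred) || nrow(target) != 2 ||
      nrow(pred) != 2 || ncol(target) != ncol(pred))
    stop("target and prediction must be 2 x N matrices on the same grid")
}

.dice_channels <- function(target, pred, eps) {
  num <- 2 * rowSums(target * pred) + eps
  den <- rowSums(target^2) + rowSums(pred^2) + eps
  num / den
}

# gradient of dice_loss wrt pred (2 x N)
.dice_loss_grad <- function(target, pred, eps = 1e-6) {
  num <- 2 * rowSums(target * pred) + eps
  den <- rowSums(target^2) + rowSums(pred^2) + eps
  # dD_c/dp_c = (2 t den - num * 2 p) / den^2 ; dL/dp = -dD/dp / 2
  -( (2 * target * den - 2 * pred * num) / den^2 ) / 2
}

#' Boundary-weighted SDT regression loss
#'
#' Weighted mean squared error between a target signed distance transform and
#' the predicted one: voxels within `h` mm of the brain boundary (|d| <= h)
#' get weight 1, voxels farther away get weight `b`, down-weighting the MSE
#' contribution of points far from the boundary. `mode = "usdt"` is the
#' unweighted variant (weight 1 everywhere, `b` and `h` ignored).
#'
#' @param target numeric vector/array of target signed distances (mm).
#' @param pred predicted signed distances, same length.
#' @param b down-weight factor in `[0, 1]` (default 1e-3).
#' @param h boundary band half-width in mm (default 4).
#' @param mode `"wsdt"` (weighted) or `"usdt"` (uniform weights).
#' @return scalar loss (weighted mean squared error).
#' @export
sdt_loss <- function(target, pred, b = 1e-3, h = 4, mode = c("wsdt", "usdt")) {
  mode <- match.arg(mode)
  target <- as.vector(target); pred <- as.vector(pred)
  if (length(target) != length(pred)) stop("target and prediction sizes differ")
  if (b < 0 || b > 1) stop("b must be in [0, 1]")
  if (h < 0) stop("h must be >= 0")
  w <- .sdt_weights(target, b, h, mode)
  sw <- sum(w)
  if (sw == 0)
    stop("degenerate weighting: b = 0 and no voxel within h of the boundary")
  sum(w * (target - pred)^2) / sw
}

.sdt_weights <- function(target, b, h, mode) {
  if (mode == "usdt") rep(1, length(target))
  else ifelse(abs(target) <= h, 1, b)
}

.sdt_loss_grad <- function(target, pred, b, h, mode) {
  w <- .sdt_weights(as.vector(target), b, h, mode)
  2 * w * (as.vector(pred) - as.vector(target)) / sum(w)
}

# one-hot 2-channel target from a mask array/vector (row 1 brain)
.mask_to_2ch <- function(mask) {
  m <- as.numeric(as.vector(mask) != 0)
  rbind(m, 1 - m)
}
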