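# Independent brute-force oracles. These deliberately avoid the package's
# C++ kernels: morphology is done with whole-array shifts, distances with
# all-pairs enumeration.

# shift a logical array by one voxel along an axis, filling with `fill`
shift_arr <- function(a, axis, by, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  idx_src <- lapply(d, seq_len)
  idx_dst <- idx_src
  n <- d[axis]
  if (abs(by) >= n) return(out)
  if (by > 0) {
    idx_dst[[axis]] <- (by + 1):n
    idx_src[[axis]] <- 1:(n - by)
  } else if (by < 0) {
    idx_dst[[axis]] <- 1:(n + by)
    idx_src[[axis]] <- (1 - by):n
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

.neighbor_shifts <- function(conn) {
  sh <- list()
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    ad <- abs(dx) + abs(dy) + abs(dz)
    if (ad == 0) next
    if (conn == 6 && ad != 1) next
    sh[[length(sh) + 1]] <- c(dx, dy, dz)
  }
  sh
}

shift3 <- function(a, dxyz, fill) {
  out <- a
  for (ax in 1:3)
    if (dxyz[ax] != 0) out <- shift_arr(out, ax, dxyz[ax], fill)
  out
}

brute_dilate <- function(m, iters = 1, conn = 6) {
  sh <- .neighbor_shifts(conn)
  for (i in seq_len(iters)) {
    acc <- m
    for (s in sh) acc <- acc | shift3(m, s, FALSE)
    m <- acc
  }
  m
}

# border_fg: voxels beyond the grid count as foreground
brute_erode <- function(m, iters = 1, conn = 6, border_fg = FALSE) {
  sh <- .neighbor_shifts(conn)
  for (i in seq_len(iters)) {
    acc <- m
    for (s in sh) acc <- acc & shift3(m, s, border_fg)
    m <- acc
  }
  m
}

# flood-fill background from the border by repeated constrained dilation
brute_fill_holes <- function(m) {
  d <- dim(m)
  seed <- array(FALSE, d)
  seed[1, , ] <- seed[d[1], , ] <- TRUE
  seed[, 1, ] <- seed[, d[2], ] <- TRUE
  seed[, , 1] <- seed[, , d[3]] <- TRUE
  outside <- seed & !m
  repeat {
    grown <- brute_dilate(outside, 1, 6) & !m
    if (identical(grown, outside)) break
    outside <- grown
  }
  m | !outside
}

# closing on an unbounded domain: pad, dilate, erode, crop, then fill
brute_close_fill <- function(m, iters, conn = 6) {
  d <- dim(m)
  pad <- iters + 1
  pm <- array(FALSE, d + 2 * pad)
  pm[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- m
  pm <- brute_erode(brute_dilate(pm, iters, conn), iters, conn)
  brute_fill_holes(pm[pad + seq_len(d[1]), pad + seq_len(d[2]),
                      pad + seq_len(d[3])])
}

# boundary voxels: mask voxels with an in-grid background face neighbor
brute_boundary <- function(m) {
  inner <- brute_erode(m, 1, 6, border_fg = TRUE)
  m & !inner
}

# all-pairs signed Euclidean distance to the boundary, world units
brute_sdt <- function(m, spacing = c(1, 1, 1)) {
  d <- dim(m)
  bnd <- which(brute_boundary(m))
  stopifnot(length(bnd) > 0)
  bc <- sweep(arrayInd(bnd, d), 2, spacing, "*")
  all_c <- sweep(arrayInd(seq_len(prod(d)), d), 2, spacing, "*")
  dist <- sqrt(pmax(outer(rowSums(all_c^2), rowSums(bc^2), "+") -
                      2 * all_c %*% t(bc), 0))
  mind <- apply(dist, 1, min)
  array(ifelse(as.vector(m), -mind, mind), d)
}

brute_hausdorff <- function(ma, mb, spacing = c(1, 1, 1), percentile = 100) {
  d <- dim(ma)
  pa <- sweep(arrayInd(which(brute_boundary(ma)), d), 2, spacing, "*")
  pb <- sweep(arrayInd(which(brute_boundary(mb)), d), 2, spacing, "*")
  dm <- sqrt(pmax(outer(rowSums(pa^2), rowSums(pb^2), "+") -
                    2 * pa %*% t(pb), 0))
  dab <- apply(dm, 1, min)
  dba <- apply(dm, 2, min)
  stat <- function(x) if (percentile == 100) max(x) else
    unname(quantile(x, percentile / 100, type = 7))
  max(stat(dab), stat(dba))
}

# random blobby label map: a few random boxes/ellipsoids over brain / csf /
# nonbrain roles on a small grid
random_labelmap <- function(n, seed, n_blobs = 4) {
  set.seed(seed)
  lab <- array(0L, c(n, n, n))
  co <- arrayInd(seq_len(n^3), c(n, n, n))
  for (b in seq_len(n_blobs)) {
    ctr <- runif(3, 0.2 * n, 0.8 * n)
    rad <- runif(3, 0.1 * n, 0.3 * n)
    inside <- rowSums(sweep(sweep(co, 2, ctr), 2, rad, "/")^2) <= 1
    lab[inside] <- sample(c(1L, 2L, 3L), 1)
  }
  roles <- data.frame(label_id = 0:3,
                      name = c("background", "brain_a", "brain_b", "csf"),
                      role = c("nonbrain", "brain", "brain", "csf_nonvent"),
                      stringsAsFactors = FALSE)
  label_map(lab, roles = roles[roles$label_id %in% c(0, unique(as.vector(lab))), ])
}

random_mask <- function(n, seed, p = NULL) {
  set.seed(seed)
  m <- array(FALSE, c(n, n, n))
  co <- arrayInd(seq_len(n^3), c(n, n, n))
  for (b in 1:2) {
    ctr <- runif(3, 0.25 * n, 0.75 * n)
    rad <- runif(3, 0.15 * n, 0.35 * n)
    m <- m | array(rowSums(sweep(sweep(co, 2, ctr), 2, rad, "/")^2) <= 1,
                   c(n, n, n))
  }
  m
}
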