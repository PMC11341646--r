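# Freehand 3D reconstruction: temporal alignment by cross-correlation, a
# PCA-defined reconstruction grid, nearest-neighbour pixel binning and
# nearest-filled hole filling.

#' Temporal offset between image and encoder signals
#'
#' Both series are linearly detrended, then the lag maximizing the
#' normalized cross-correlation is returned in seconds. Sign convention:
#' positive means the image signal lags the encoder. Ties are resolved
#' toward the smallest absolute lag.
#'
#' @param imageSignal,encoderSignal numeric series sampled at `rate`, length
#'   >= 8.
#' @param rate sampling rate in Hz.
#' @return offset in seconds.
#' @export
estimateTimeOffset <- function(imageSignal, encoderSignal, rate) {
  n <- length(imageSignal)
  if (n < 8L || length(encoderSignal) < 8L)
    stop("both series must have length >= 8")
  if (length(encoderSignal) != n)
    stop("series must have equal length")
  detrend <- function(y) stats::residuals(stats::lm(y ~ seq_along(y)))
  a <- detrend(imageSignal)
  b <- detrend(encoderSignal)
  tol <- 1e-10 * max(1, abs(imageSignal), abs(encoderSignal))
  if (stats::sd(a) < tol || stats::sd(b) < tol) stop("no signal variance")
  lags <- seq(-(n - 1L), n - 1L)
  den <- sqrt(sum(a^2) * sum(b^2)) # global normalization (ccf-style)
  cc <- vapply(lags, function(l) {
    # c(l) ~ sum_t image[t] * encoder[t - l] over the overlap
    ti <- if (l >= 0) (1 + l):n else 1:(n + l)
    sum(a[ti] * b[ti - l]) / den
  }, numeric(1))
  best <- which(cc >= max(cc) - 1e-12)
  lag <- lags[best[order(abs(lags[best]), lags[best])[1]]]
  lag / rate
}

# linear pose interpolation at arbitrary times: translations componentwise,
# rotations entrywise (small-angle) followed by SVD re-orthonormalization
.interp_poses <- function(poses, times) {
  tp <- poses@timestamps
  n <- length(tp)
  R <- array(0, c(3, 3, length(times)))
  Tr <- matrix(0, length(times), 3)
  for (k in seq_along(times)) {
    t0 <- min(max(times[k], tp[1]), tp[n])
    i <- findInterval(t0, tp, rightmost.closed = TRUE)
    i <- min(max(i, 1L), n - 1L)
    if (n == 1L) { i <- 1L; f <- 0 }
    else f <- (t0 - tp[i]) / (tp[i + 1] - tp[i])
    if (n == 1L) {
      Rk <- poses@rotations[, , 1]; Tk <- poses@translations[1, ]
    } else {
      Rk <- (1 - f) * poses@rotations[, , i] + f * poses@rotations[, , i + 1]
      Tk <- (1 - f) * poses@translations[i, ] + f * poses@translations[i + 1, ]
    }
    sv <- svd(Rk)
    Rk <- sv$u %*% t(sv$v)
    if (det(Rk) < 0) { sv$u[, 3] <- -sv$u[, 3]; Rk <- sv$u %*% t(sv$v) }
    R[, , k] <- Rk
    Tr[k, ] <- Tk
  }
  list(rotations = R, translations = Tr)
}

# world coordinates of the four corners of every frame
.frame_corners <- function(stack, ip) {
  d <- dim(stack@frames[[1]])
  px <- stack@pixelSpacing
  corners <- rbind(c(0, 0, 0), c((d[1] - 1) * px[1], 0, 0),
                   c(0, (d[2] - 1) * px[2], 0),
                   c((d[1] - 1) * px[1], (d[2] - 1) * px[2], 0))
  n <- length(stack@frames)
  out <- matrix(0, 4 * n, 3)
  for (k in seq_len(n))
    out[(4 * k - 3):(4 * k), ] <-
      corners %*% t(ip$rotations[, , k]) +
      matrix(ip$translations[k, ], 4, 3, byrow = TRUE)
  out
}

.fix_axis_sign <- function(e, refs, tiebreak) {
  for (r in refs) {
    d <- sum(e * r)
    if (abs(d) > 1e-9) return(if (d < 0) -e else e)
  }
  for (r in tiebreak) {
    d <- sum(e * r)
    if (abs(d) > 1e-9) return(if (d < 0) -e else e)
  }
  e
}

#' Define the reconstruction grid by PCA on frame corners
#'
#' The grid axes are the principal axes of the world-space corner points of
#' all frames (poses interpolated to frame timestamps), associated with
#' (image x, image y, sweep) by maximal parallelism so the requested
#' spacing means (in-plane x, in-plane y, slice distance); signs are fixed
#' toward the mean image axes / sweep direction (ties toward +z) and the
#' third axis completes a right-handed basis. Origin and dims form the
#' tight bounding box of the corner cloud in PCA space, expanded to whole
#' voxels.
#'
#' @param stack a [FrameStack-class] (>= 2 frames).
#' @param poses a [PoseSequence-class].
#' @param spacing target voxel size (mm), length 3.
#' @return A [VolumeGrid-class].
#' @export
defineGrid <- function(stack, poses, spacing) {
  if (length(stack@frames) < 2L) stop("at least 2 frames required")
  ip <- .interp_poses(poses, stack@timestamps)
  pts <- .frame_corners(stack, ip)
  ev <- eigen(stats::cov(pts), symmetric = TRUE)
  if (ev$values[2] <= 1e-12 * max(ev$values, 1e-300))
    stop("degenerate corner cloud: corner points are collinear")
  n <- length(stack@frames)
  sweep_dir <- ip$translations[n, ] - ip$translations[1, ]
  img_x <- rowMeans(vapply(seq_len(n), function(k) ip$rotations[, 1, k],
                           numeric(3)))
  img_y <- rowMeans(vapply(seq_len(n), function(k) ip$rotations[, 2, k],
                           numeric(3)))
  # associate each principal axis with the reference direction (image x,
  # image y, sweep) it is most parallel to, so the requested spacing lands
  # on (in-plane x, in-plane y, slice distance); variance order is the
  # fallback when the assignment is ambiguous
  refs <- list(img_x, img_y, sweep_dir)
  refs <- lapply(refs, function(r) r / max(sqrt(sum(r^2)), 1e-300))
  dots <- vapply(refs, function(r)
    abs(as.numeric(t(ev$vectors) %*% r)), numeric(3))
  ord <- integer(3)
  taken <- rep(FALSE, 3L)
  for (j in 1:3) {
    cand <- which.max(ifelse(taken, -Inf, dots[, j]))
    ord[j] <- cand
    taken[cand] <- TRUE
  }
  if (anyDuplicated(ord)) ord <- 1:3
  tiebreak <- list(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0))
  e1 <- .fix_axis_sign(ev$vectors[, ord[1]], list(img_x, img_y, sweep_dir),
                       tiebreak)
  e2 <- .fix_axis_sign(ev$vectors[, ord[2]], list(img_y, img_x, sweep_dir),
                       tiebreak)
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  E <- cbind(e1, e2, e3, deparse.level = 0)
  tt <- pts %*% E
  tmin <- apply(tt, 2, min)
  tmax <- apply(tt, 2, max)
  dims <- as.integer(ceiling((tmax - tmin) / spacing - 1e-9)) + 1L
  new("VolumeGrid", origin = as.numeric(E %*% tmin), axes = E,
      spacing = as.numeric(spacing), dims = dims)
}

#' Reconstruct a volume from a tracked frame stack
#'
#' Pass 1 maps every frame pixel to its nearest voxel (collisions averaged);
#' pass 2 assigns each remaining empty voxel the value of its nearest filled
#' voxel within `fillRadius` steps. Voxels never reached stay 0 and are
#' flagged in the returned coverage mask.
#'
#' @param stack a [FrameStack-class].
#' @param poses a [PoseSequence-class].
#' @param grid a [VolumeGrid-class] covering the stack footprint.
#' @param fillRadius hole-fill search bound in voxels (default 3).
#' @return list with `volume` ([ScanVolume-class]) and `coverage`
#'   ([MaskVolume-class], TRUE where a value was assigned in either pass).
#' @export
reconstructVolume <- function(stack, poses, grid, fillRadius = 3L) {
  if (!length(stack@frames)) stop("empty stack")
  ip <- .interp_poses(poses, stack@timestamps)
  d <- dim(stack@frames[[1]])
  px <- stack@pixelSpacing
  nvox <- prod(grid@dims)
  sums <- numeric(nvox)
  cnts <- numeric(nvox)
  ij <- cbind(rep(seq_len(d[1]) - 1, d[2]),
              rep(seq_len(d[2]) - 1, each = d[1]))
  plane <- cbind(ij[, 1] * px[1], ij[, 2] * px[2], 0)
  for (k in seq_along(stack@frames)) {
    w <- plane %*% t(ip$rotations[, , k])
    w <- sweep(w, 2, ip$translations[k, ], "+")
    # project into grid coordinates: t = E'(w - origin)
    tt <- sweep(w, 2, grid@origin, "-") %*% grid@axes
    idx <- round(sweep(tt, 2, grid@spacing, "/"))
    ok <- idx[, 1] >= 0 & idx[, 1] < grid@dims[1] &
          idx[, 2] >= 0 & idx[, 2] < grid@dims[2] &
          idx[, 3] >= 0 & idx[, 3] < grid@dims[3]
    if (!any(ok)) next
    lin <- idx[ok, 1] + grid@dims[1] * (idx[ok, 2] + grid@dims[2] * idx[ok, 3]) + 1
    vals <- as.vector(stack@frames[[k]])[ok]
    agg <- rowsum(cbind(vals, 1), lin)
    at <- as.integer(rownames(agg))
    sums[at] <- sums[at] + agg[, 1]
    cnts[at] <- cnts[at] + agg[, 2]
  }
  if (!any(cnts > 0)) stop("no pixel lands in grid")
  vol <- array(ifelse(cnts > 0, sums / pmax(cnts, 1), 0), grid@dims)
  filled <- array(cnts > 0, grid@dims)
  nf <- cpp_nn_fill(vol, as.vector(filled), as.integer(fillRadius),
                    grid@spacing)
  out <- array(nf$values, grid@dims)
  coverage <- array(nf$filled, grid@dims)
  out[!coverage] <- 0
  list(volume = ScanVolume(out, spacing = grid@spacing,
                           origin = grid@origin, axes = grid@axes),
       coverage = MaskVolume(coverage, spacing = grid@spacing,
                             origin = grid@origin, axes = grid@axes))
}
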