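# From filtered volume to pruned, smoothed direction field: muscle-frame
# PCA and rotation, 3D Hessian eigenanalysis, the pruning cascade and
# whole-muscle fill.

.pca_world <- function(mask, minVoxels = 4L) {
  idx <- which(mask@data, arr.ind = TRUE) - 1L
  if (nrow(idx) < minVoxels)
    stop("mask too small: fewer than ", minVoxels, " voxels")
  w <- voxelToWorld(mask, idx)
  ev <- eigen(stats::cov(w), symmetric = TRUE)
  list(values = ev$values, vectors = ev$vectors, centroid = colMeans(w))
}

.sign_fix <- function(e, refs) {
  for (r in refs) {
    d <- sum(e * r)
    if (abs(d) > 1e-9) return(if (d < 0) -e else e)
  }
  e
}

#' Muscle coordinate frame from the whole-muscle mask
#'
#' Principal axes of the mask voxels' world coordinates, ordered by
#' decreasing variance. The largest axis is sign-fixed toward the volume's
#' +z axis (ties: +y, then +x), the second toward +y, and the third
#' completes a right-handed basis.
#'
#' @param mask whole-muscle [MaskVolume-class].
#' @param allowDegenerate return an arbitrary (but valid) frame instead of
#'   erroring when the covariance is near-isotropic.
#' @return A [MuscleFrame-class].
#' @export
muscleFrame <- function(mask, allowDegenerate = FALSE) {
  p <- .pca_world(mask)
  rel <- p$values / max(p$values)
  if (max(p$values) <= 0 ||
      (!allowDegenerate && (rel[1] - rel[2]) < 1e-6 &&
       (rel[2] - rel[3]) < 1e-6))
    stop("degenerate mask covariance: principal axes are not unique ",
         "(set allowDegenerate = TRUE to accept an arbitrary frame)")
  A <- gridAxes(mask)
  # the two cross-section axes can have near-equal variance; associate the
  # second axis with the image depth (+y) direction so the recovered frame
  # is stable for near-symmetric cross-sections
  v2 <- p$vectors[, 2]
  v3 <- p$vectors[, 3]
  if (abs(sum(v3 * A[, 2])) > abs(sum(v2 * A[, 2]))) {
    tmp <- v2; v2 <- v3; v3 <- tmp
  }
  e1 <- .sign_fix(p$vectors[, 1], list(A[, 3], A[, 2], A[, 1]))
  e2 <- .sign_fix(v2, list(A[, 2], A[, 3], A[, 1]))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  new("MuscleFrame", rotation = cbind(e1, e2, e3, deparse.level = 0),
      centroid = p$centroid)
}

.rotated_grid <- function(vol, frame) {
  # new grid axes: muscle long axis becomes z so yz is the fascicle plane;
  # the first (x) axis is flipped if needed to keep a right-handed grid
  A <- frame@rotation[, c(3, 2, 1)]
  if (det(A) < 0) A[, 1] <- -A[, 1]
  d <- dims(vol)
  corners <- as.matrix(expand.grid(c(0, d[1] - 1), c(0, d[2] - 1),
                                   c(0, d[3] - 1)))
  w <- voxelToWorld(vol, corners)
  tt <- w %*% A
  tmin <- apply(tt, 2, min)
  tmax <- apply(tt, 2, max)
  ndims <- as.integer(ceiling((tmax - tmin) / spacing(vol) - 1e-9)) + 1L
  list(axes = A, origin = as.numeric(A %*% tmin), dims = ndims)
}

.resample_to_grid <- function(data, src, g, nearest = FALSE, fill = 0) {
  idx <- as.matrix(expand.grid(seq_len(g$dims[1]) - 1,
                               seq_len(g$dims[2]) - 1,
                               seq_len(g$dims[3]) - 1))
  w <- sweep(sweep(idx, 2, spacing(src), "*") %*% t(g$axes), 2, g$origin, "+")
  co <- worldToVoxel(src, w)
  co[abs(co - round(co)) < 1e-9] <- round(co[abs(co - round(co)) < 1e-9])
  vals <- if (nearest) cpp_nearest(.as_cube(data), co, fill)
          else cpp_trilinear(.as_cube(data), co, fill)
  array(vals, g$dims)
}

#' Resample a volume into the muscle coordinate system
#'
#' Linear interpolation for intensities, nearest-neighbour for masks; the
#' output grid has the muscle long axis along z, the same spacing, and
#' covers the rotated bounding box of the input.
#'
#' @param vol a [ScanVolume-class] or [MaskVolume-class].
#' @param frame a [MuscleFrame-class].
#' @return resampled object of the same class.
#' @export
rotateVolume <- function(vol, frame) {
  g <- .rotated_grid(vol, frame)
  if (is(vol, "MaskVolume")) {
    data <- .resample_to_grid(array(as.double(vol@data), dims(vol)), vol, g,
                              nearest = TRUE)
    return(MaskVolume(array(data > 0.5, g$dims), spacing = spacing(vol),
                      origin = g$origin, axes = g$axes))
  }
  stopifnot(is(vol, "ScanVolume"))
  data <- .resample_to_grid(vol@data, vol, g)
  ScanVolume(data, spacing = spacing(vol), origin = g$origin, axes = g$axes,
             scaleFactor = vol@scaleFactor)
}

# canonicalize eigenvector signs to the hemisphere with positive component
# along the long axis (ties: +z, then +y, then +x)
.canonicalize_signs <- function(v, axis = c(0, 0, 1)) {
  dp <- v[, 1] * axis[1] + v[, 2] * axis[2] + v[, 3] * axis[3]
  flip <- dp < 0
  tie <- abs(dp) < 1e-12
  if (any(tie)) {
    for (j in c(3, 2, 1)) {
      cmp <- v[tie, j]
      flip[tie][cmp < 0 & abs(cmp) > 1e-12] <- TRUE
      tie[tie] <- abs(cmp) <= 1e-12
      if (!any(tie)) break
    }
  }
  v[flip, ] <- -v[flip, ]
  v
}

#' Per-voxel fascicle directions from 3D Hessian eigenanalysis
#'
#' Smooths the (re-stitched, filtered) volume with a 3D Gaussian of
#' `hessianSigma` voxels, computes the Hessian by Gaussian second
#' derivatives, and takes per voxel the unit eigenvector of the
#' smallest-magnitude eigenvalue as the fascicle direction (along a bright
#' ridge the second derivative vanishes along the fibre while the
#' cross-fibre eigenvalues are strongly negative). `mode = "signed"` takes
#' the signed-smallest eigenvalue instead, for auditing. Near-degenerate
#' voxels (isotropic blobs) are flagged, not removed.
#'
#' @param filtered a [ScanVolume-class] (MVEF output).
#' @param hessianSigma Gaussian scale in voxels (default 2).
#' @param mode `"magnitude"` (default) or `"signed"`.
#' @param mask optional logical array restricting evaluation.
#' @param canonicalAxis hemisphere axis for sign canonicalization.
#' @param degenTol relative eigenvalue-gap threshold for the degeneracy
#'   flag.
#' @return list with `field` ([DirectionField-class], unit vectors) and
#'   `degenerate` (logical array).
#' @export
directionField <- function(filtered, hessianSigma = 2,
                           mode = c("magnitude", "signed"), mask = NULL,
                           canonicalAxis = c(0, 0, 1), degenTol = 0.05) {
  stopifnot(is(filtered, "ScanVolume"))
  mode <- match.arg(mode)
  d <- dims(filtered)
  if (is.null(mask)) mask <- array(TRUE, d)
  H <- .hessian3(.gauss3(filtered@data, hessianSigma), hessianSigma)
  eg <- cpp_eig3_field(H$xx, H$xy, H$xz, H$yy, H$yz, H$zz, as.vector(mask),
                       mode == "magnitude", degenTol)
  v <- cbind(eg$vx, eg$vy, eg$vz)
  fin <- is.finite(v[, 1])
  v[fin, ] <- .canonicalize_signs(v[fin, , drop = FALSE], canonicalAxis)
  vec <- array(NaN, c(d, 3))
  vec[, , , 1] <- v[, 1]; vec[, , , 2] <- v[, 2]; vec[, , , 3] <- v[, 3]
  list(field = DirectionField(vec, spacing = spacing(filtered),
                              origin = origin(filtered),
                              axes = gridAxes(filtered)),
       degenerate = array(eg$degenerate & as.vector(mask), d))
}

#' Binarize the filtered volume and shrink the compartment mask
#'
#' Voxels at or above `binarizeFraction` of the maximum filtered value are
#' kept (the tie at exactly the threshold is inclusive) and intersected
#' with the compartment mask eroded by `shrinkVoxels` iterations of the
#' 6-connected structuring element.
#'
#' @param filtered [ScanVolume-class] (MVEF output).
#' @param compartment [MaskVolume-class], same geometry.
#' @param p a [PruneParams-class].
#' @return A [MaskVolume-class].
#' @export
fascicleMask <- function(filtered, compartment, p = PruneParams()) {
  .stopifnot_same_geometry(filtered, compartment,
                           "filtered volume and compartment")
  mx <- max(filtered@data)
  if (mx <= 0) stop("all-zero filtered volume")
  keep <- filtered@data >= p@binarizeFraction * mx
  comp <- compartment@data
  if (p@shrinkVoxels > 0L)
    comp <- array(cpp_erode6(as.vector(comp), dim(comp), p@shrinkVoxels),
                  dim(comp))
  MaskVolume(keep & comp, spacing = spacing(filtered),
             origin = origin(filtered), axes = gridAxes(filtered))
}

#' Anisotropic length scaling and 50%-length pruning
#'
#' Applies the mask (voxels outside become missing), multiplies each unit
#' vector's components elementwise by the voxel spacing — mapping
#' index-space directions to physical (mm) directions — removes vectors
#' whose scaled length falls below `lengthFraction` of the field maximum,
#' and re-normalizes the survivors to unit length.
#'
#' @param field unit-vector [DirectionField-class].
#' @param mask [MaskVolume-class] applied before scaling.
#' @param lengthFraction pruning fraction (default 0.5).
#' @return A [DirectionField-class].
#' @export
scaleAndPruneLengths <- function(field, mask, lengthFraction = 0.5) {
  .stopifnot_same_geometry(field, mask, "field and mask")
  v <- matrix(field@vectors, ncol = 3)
  v[!as.vector(mask@data), ] <- NaN
  if (!any(is.finite(v[, 1]))) stop("empty field after masking")
  sp <- spacing(field)
  v <- sweep(v, 2, sp, "*")
  nrm <- sqrt(rowSums(v^2))
  mx <- max(nrm, na.rm = TRUE)
  v[!is.na(nrm) & nrm < lengthFraction * mx, ] <- NaN
  nrm <- sqrt(rowSums(v^2))
  v <- v / nrm # unit length for downstream angle math
  DirectionField(array(v, c(dims(field), 3)), spacing = sp,
                 origin = origin(field), axes = gridAxes(field))
}

#' Remove line endpoints by neighbour count
#'
#' A voxel survives iff at least `minNeighbors` of its 26-neighbourhood are
#' non-missing in the input field (a single simultaneous pass; a voxel with
#' exactly `minNeighbors` neighbours is kept).
#'
#' @param field a [DirectionField-class].
#' @param minNeighbors threshold (default 18).
#' @return A [DirectionField-class].
#' @export
pruneEndpoints <- function(field, minNeighbors = 18L) {
  sup <- supportMask(field)
  cnt <- array(cpp_count_neighbors26(as.vector(sup), dim(sup)), dim(sup))
  v <- field@vectors
  drop <- sup & cnt < minNeighbors
  for (comp in 1:3) {
    vc <- v[, , , comp]
    vc[drop] <- NaN
    v[, , , comp] <- vc
  }
  DirectionField(v, spacing = spacing(field), origin = origin(field),
                 axes = gridAxes(field))
}

# componentwise 1D linear interpolation along each grid axis; exact for
# affine fields wherever a missing voxel is bracketed by support along an
# axis. Returns the mean of the per-axis estimates (NaN where none).
.axis_interp <- function(comp, support, target) {
  d <- dim(comp)
  ssum <- array(0, d)
  scnt <- array(0L, d)
  for (axis in 1:3) {
    perm <- c(axis, setdiff(1:3, axis))
    a <- aperm(comp, perm)
    s <- aperm(support, perm)
    tg <- aperm(target, perm)
    n <- dim(a)[1]
    m <- prod(dim(a)[2:3])
    dim(a) <- c(n, m); dim(s) <- c(n, m); dim(tg) <- c(n, m)
    est <- array(NaN, c(n, m))
    cols <- which(colSums(s) >= 2 & colSums(tg & !s) > 0)
    for (j in cols) {
      xi <- which(s[, j])
      xo <- which(tg[, j] & !s[, j])
      xo <- xo[xo > xi[1] & xo < xi[length(xi)]]
      if (!length(xo)) next
      est[xo, j] <- stats::approx(xi, a[xi, j], xout = xo)$y
    }
    dim(est) <- dim(aperm(comp, perm))
    est <- aperm(est, order(perm))
    ok <- is.finite(est)
    ssum[ok] <- ssum[ok] + est[ok]
    scnt[ok] <- scnt[ok] + 1L
  }
  out <- array(NaN, d)
  got <- scnt > 0L
  out[got] <- ssum[got] / scnt[got]
  out
}

#' Fill the whole muscle with directions
#'
#' Componentwise linear interpolation on the gridded field (axis-line
#' interpolation, exact for affine variation) fills mask voxels bracketed
#' by support; the remaining mask voxels are extrapolated by the penalized
#' least-squares smoother with the small parameter `sp@sExtrap`. The result
#' is re-normalized to unit vectors and covers every mask voxel.
#'
#' @param field detected [DirectionField-class].
#' @param muscleMask [MaskVolume-class] to cover.
#' @param sp a [SmoothParams-class] (`sExtrap` is used).
#' @return A [DirectionField-class] non-missing exactly on the mask.
#' @export
fillMuscle <- function(field, muscleMask, sp = SmoothParams()) {
  .stopifnot_same_geometry(field, muscleMask, "field and mask")
  sup <- supportMask(field)
  if (sum(sup) < 4L) stop("insufficient support: need >= 4 support voxels")
  idx <- which(sup, arr.ind = TRUE)
  if (qr(sweep(idx, 2, colMeans(idx)))$rank < 3L)
    stop("insufficient support: support voxels are coplanar")
  target <- muscleMask@data & !sup
  d <- dims(field)
  out <- field@vectors
  needSmooth <- NULL
  for (comp in 1:3) {
    vc <- out[, , , comp]
    est <- .axis_interp(vc, sup, target)
    fill1 <- target & is.finite(est)
    vc[fill1] <- est[fill1]
    remaining <- muscleMask@data & !is.finite(vc)
    if (any(remaining)) {
      sm <- .smooth_array(vc, sp@sExtrap, maxIter = sp@maxIter,
                          tol = sp@tol)
      vc[remaining] <- sm[remaining]
    }
    vc[!muscleMask@data] <- NaN
    out[, , , comp] <- vc
  }
  v <- matrix(out, ncol = 3)
  nrm <- sqrt(rowSums(v^2))
  bad <- is.finite(nrm) & nrm < 1e-12
  if (any(bad)) {
    mdir <- colMeans(v[is.finite(nrm) & nrm >= 1e-12, , drop = FALSE])
    mdir <- mdir / sqrt(sum(mdir^2))
    v[bad, ] <- matrix(mdir, sum(bad), 3, byrow = TRUE)
    nrm[bad] <- 1
  }
  v <- v / nrm
  DirectionField(array(v, c(d, 3)), spacing = spacing(field),
                 origin = origin(field), axes = gridAxes(field))
}
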