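# Synthetic scenes with exact ground truth: a two-group wire phantom and a
# two-compartment pennate muscle, both imaged through a simple ultrasound
# forward model (PSF blur + multiplicative speckle surrogate + additive
# noise).

#' Apply the speckle/noise forward model to a volume
#'
#' Anisotropic Gaussian PSF blur (axial sigma along the beam axis y, lateral
#' sigma along x and the elevational axis z), multiplication by
#' `1 + N(0, multSigma)`, addition of `N(0, addSigma)` and clipping to
#' `[0, 255]`. Deterministic given `seed`; all-zero sigmas reduce to the
#' identity (up to clipping).
#'
#' @param vol a [ScanVolume-class].
#' @param p a [SpeckleParams-class].
#' @param seed RNG seed.
#' @return noisy [ScanVolume-class].
#' @export
addSpeckle <- function(vol, p = SpeckleParams(), seed = 1L) {
  stopifnot(is(vol, "ScanVolume"))
  data <- vol@data
  sig_vox <- c(p@psfSigma[2], p@psfSigma[1], p@psfSigma[2]) / vol@spacing
  data <- .gauss3(data, sig_vox)
  if (p@multSigma > 0 || p@addSigma > 0) {
    old <- globalenv()$.Random.seed
    set.seed(seed)
    n <- length(data)
    if (p@multSigma > 0)
      data <- data * (1 + array(stats::rnorm(n, 0, p@multSigma), dim(data)))
    if (p@addSigma > 0)
      data <- data + array(stats::rnorm(n, 0, p@addSigma), dim(data))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  ScanVolume(pmin(pmax(data, 0), 255), spacing = vol@spacing,
             origin = vol@origin, axes = vol@axes)
}

# Rasterize a line segment as an anti-aliased bright tube: centreline
# samples every half-voxel splat trilinear weights into `acc` (elementwise
# maximum), so a centreline through a voxel centre reaches weight 1.
.splat_wire <- function(acc, p0, p1, spacing) {
  L <- sqrt(sum((p1 - p0)^2))
  nstep <- max(2L, ceiling(L / (0.5 * min(spacing))))
  t <- seq(0, 1, length.out = nstep)
  pts <- cbind(p0[1] + t * (p1[1] - p0[1]), p0[2] + t * (p1[2] - p0[2]),
               p0[3] + t * (p1[3] - p0[3]))
  idx <- sweep(pts, 2, spacing, "/") # continuous 0-based voxel coords
  d <- dim(acc)
  lo <- floor(idx)
  fr <- idx - lo
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ii <- lo[, 1] + dx; jj <- lo[, 2] + dy; kk <- lo[, 3] + dz
    wgt <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
           (if (dy) fr[, 2] else 1 - fr[, 2]) *
           (if (dz) fr[, 3] else 1 - fr[, 3])
    ok <- ii >= 0 & ii < d[1] & jj >= 0 & jj < d[2] & kk >= 0 & kk < d[3]
    if (!any(ok)) next
    lin <- ii[ok] + d[1] * (jj[ok] + d[2] * kk[ok]) + 1
    w <- wgt[ok]
    m <- vapply(split(w, lin), max, numeric(1))
    at <- as.integer(names(m))
    acc[at] <- pmax(acc[at], m)
  }
  acc
}

#' Generate a synthetic wire phantom with known ground truth
#'
#' Two wire groups (a `rowsA` x `colsA` array and `nB` wires side by side,
#' hole pitch 2.5 mm, wire diameter 0.1 mm) run nearly along the sweep axis
#' z, tilted symmetrically in the xz-plane so the angle between the groups
#' equals `spec@interGroupAngle` exactly. Wires are rasterized as bright
#' anti-aliased tubes in darker water, speckle is applied with the spec
#' seed, and per-group bounding-box compartment masks are returned.
#'
#' @param spec a [WirePhantomSpec-class].
#' @return list with `volume` ([ScanVolume-class]), `clean` (noise-free
#'   volume) and `truth` ([GroundTruth-class]: unit group directions `A`,
#'   `B`, the true angle and the compartment masks).
#' @export
generateWirePhantom <- function(spec = WirePhantomSpec()) {
  sp <- spec@spacing
  h <- spec@interGroupAngle / 2 * pi / 180
  dA <- c(-sin(h), 0, cos(h))
  dB <- c(sin(h), 0, cos(h))
  L <- spec@wallSeparation
  pitch <- spec@holePitch
  dxdzA <- dA[1] / dA[3] # x drift per mm of z
  dxdzB <- dB[1] / dB[3]
  tilt <- (L / 2) * abs(dxdzA)
  margin <- 1.5
  gap <- 3 * pitch # lateral gap between the two groups
  spanA <- (spec@colsA - 1) * pitch
  spanB <- (spec@nB - 1) * pitch
  x0A <- margin + tilt
  x0B <- x0A + spanA + gap
  nx <- ceiling((x0B + spanB + tilt + margin) / sp[1]) + 1
  spanY <- (spec@rowsA - 1) * pitch
  y0 <- margin
  ny <- ceiling((y0 + spanY + margin) / sp[2]) + 1
  nz <- ceiling(L / sp[3]) + 1
  dims <- as.integer(c(nx, ny, nz))
  acc <- array(0, dims)
  zmid <- (nz - 1) * sp[3] / 2
  extent <- (dims - 1) * sp
  wires <- list()
  for (r in seq_len(spec@rowsA) - 1) for (cc in seq_len(spec@colsA) - 1)
    wires[[length(wires) + 1]] <-
      list(xc = x0A + cc * pitch, yc = y0 + r * pitch, g = "A", d = dxdzA)
  yB <- y0 + spanY / 2
  for (cc in seq_len(spec@nB) - 1)
    wires[[length(wires) + 1]] <-
      list(xc = x0B + cc * pitch, yc = yB, g = "B", d = dxdzB)
  for (w in seq_along(wires)) {
    wi <- wires[[w]]
    p0 <- c(wi$xc - zmid * wi$d, wi$yc, 0)
    p1 <- c(wi$xc + (extent[3] - zmid) * wi$d, wi$yc, extent[3])
    if (any(c(p0[1], p1[1]) < 0) || any(c(p0[1], p1[1]) > extent[1]) ||
        wi$yc < 0 || wi$yc > extent[2])
      stop("wire ", w, " exits the volume")
    acc <- .splat_wire(acc, p0, p1, sp)
  }
  ints <- spec@intensities
  data <- ints[["water"]] + (ints[["wire"]] - ints[["water"]]) * acc
  clean <- ScanVolume(data, spacing = sp)
  noisy <- addSpeckle(clean, spec@noise, seed = spec@seed)
  # compartment masks: per-group bounding boxes dilated laterally
  dil <- 1.2
  xs <- (seq_len(dims[1]) - 1) * sp[1]
  ys <- (seq_len(dims[2]) - 1) * sp[2]
  boxmask <- function(xr, yr) {
    mx <- xs >= xr[1] & xs <= xr[2]
    my <- ys >= yr[1] & ys <= yr[2]
    array(outer(mx, my) , c(dims[1], dims[2], dims[3]))
  }
  mA <- boxmask(c(x0A - tilt - dil, x0A + spanA + tilt + dil),
                c(y0 - dil, y0 + spanY + dil))
  mB <- boxmask(c(x0B - tilt - dil, x0B + spanB + tilt + dil),
                c(yB - dil, yB + dil))
  maskA <- MaskVolume(mA, spacing = sp)
  maskB <- MaskVolume(mB, spacing = sp)
  truth <- new("GroundTruth",
               directions = list(A = dA, B = dB),
               trueAngle = spec@interGroupAngle,
               masks = list(A = maskA, B = maskB))
  list(volume = noisy, clean = clean, truth = truth)
}

#' Generate a synthetic two-compartment pennate muscle
#'
#' A superellipsoid envelope with its long axis along z, split by a bright
#' central aponeurosis sheet at y = 0 (thickness `apoThickness`, direction
#' +z). Each compartment contains parallel bright perimysium lines in the
#' yz-plane at the programmed pennation angle to the aponeurosis direction;
#' the ground truth holds the exact per-compartment unit directions, the
#' per-voxel angle map and all masks.
#'
#' @param spec a [PennateMuscleSpec-class].
#' @return list with `volume`, `clean`, `truth` ([GroundTruth-class] with
#'   masks `whole`, `superficial`, `deep`, `aponeurosis`).
#' @export
generatePennateMuscle <- function(spec = PennateMuscleSpec()) {
  sp <- spec@spacing
  ax <- spec@semiAxes
  if (spec@apoThickness >= ax[2])
    stop("pennation geometry incompatible with envelope: ",
         "aponeurosis sheet fills a compartment")
  margin <- 1.5
  dims <- as.integer(ceiling((2 * ax + 2 * margin) / sp) + 1)
  ctr <- (dims - 1) * sp / 2
  xs <- (seq_len(dims[1]) - 1) * sp[1] - ctr[1]
  ys <- (seq_len(dims[2]) - 1) * sp[2] - ctr[2]
  zs <- (seq_len(dims[3]) - 1) * sp[3] - ctr[3]
  e <- spec@superellipseExp
  # envelope: superellipse cross-section, elliptic taper along z
  cross <- outer((abs(xs) / ax[1])^e, (abs(ys) / ax[2])^e, "+")^(2 / e)
  env <- outer(cross, (zs / ax[3])^2, "+") <= 1
  X <- array(rep(xs, times = dims[2] * dims[3]), dims)
  Y <- array(rep(ys, each = dims[1]), dims)
  Z <- array(rep(zs, each = dims[1] * dims[2]), dims)
  half <- spec@apoThickness / 2
  apo <- env & abs(Y) <= half
  sup <- env & Y > half
  deep <- env & Y < -half
  ths <- spec@pennationSuperficial * pi / 180
  thd <- spec@pennationDeep * pi / 180
  fS <- c(0, sin(ths), cos(ths))
  fD <- c(0, -sin(thd), cos(thd))
  ints <- spec@intensities
  data <- array(ints[["background"]], dims)
  data[env] <- ints[["muscle"]]
  lineprof <- function(theta) {
    # perimysium as a lattice of bright tubes along the fascicle direction
    # (fascicle bundles are tubular, so the Hessian sees one near-zero
    # eigenvalue along the fibre, not a degenerate in-sheet pair):
    # centrelines repeat every fasciclePitch both across the yz-normal and
    # along x
    n <- c(cos(theta), -sin(theta)) # (ny, nz) unit normal in the yz-plane
    phn <- (Y * n[1] + Z * n[2]) %% spec@fasciclePitch
    dn <- pmin(phn, spec@fasciclePitch - phn)
    phx <- X %% spec@fasciclePitch
    dx <- pmin(phx, spec@fasciclePitch - phx)
    r2 <- dn^2 + dx^2
    pmax(0, 1 - r2 / (spec@lineWidth / 2)^2) # smooth tube profile
  }
  pS <- lineprof(ths)
  pD <- lineprof(-thd)
  data[sup] <- pmax(data[sup],
                    ints[["muscle"]] +
                      (ints[["line"]] - ints[["muscle"]]) * pS[sup])
  data[deep] <- pmax(data[deep],
                     ints[["muscle"]] +
                       (ints[["line"]] - ints[["muscle"]]) * pD[deep])
  data[apo] <- ints[["aponeurosis"]]
  clean <- ScanVolume(data, spacing = sp)
  noisy <- addSpeckle(clean, spec@noise, seed = spec@seed)
  angleMap <- array(NaN, dims)
  angleMap[sup] <- spec@pennationSuperficial
  angleMap[deep] <- spec@pennationDeep
  angleMap[apo] <- 0
  truth <- new("GroundTruth",
               directions = list(superficial = fS, deep = fD),
               trueAngle = NA_real_,
               angleMap = angleMap,
               masks = list(whole = MaskVolume(env, spacing = sp),
                            superficial = MaskVolume(sup, spacing = sp),
                            deep = MaskVolume(deep, spacing = sp),
                            aponeurosis = MaskVolume(apo, spacing = sp)),
               apoDirection = c(0, 0, 1))
  list(volume = noisy, clean = clean, truth = truth)
}
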