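# Pennation angles, phantom angle statistics, muscle volume and summaries.

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero-length vector")
  v / n
}

.folded_angle_deg <- function(dots) {
  acos(pmin(pmax(abs(dots), 0), 1)) * 180 / pi
}

#' Aponeurosis direction from its mask
#'
#' First principal axis of the mask voxels' world coordinates, expressed in
#' the grid frame and sign-canonicalized toward the muscle long axis.
#'
#' @param apoMask aponeurosis [MaskVolume-class] (>= 4 non-collinear
#'   voxels).
#' @param longAxis hemisphere reference in the grid frame (default +z).
#' @return unit 3-vector (grid-frame components).
#' @export
aponeurosisDirection <- function(apoMask, longAxis = c(0, 0, 1)) {
  p <- .pca_world(apoMask)
  if (p$values[1] <= 1e-12)
    stop("degenerate aponeurosis mask: no spatial extent")
  e1 <- t(gridAxes(apoMask)) %*% p$vectors[, 1] # world -> grid frame
  e1 <- as.numeric(e1)
  d <- sum(e1 * longAxis)
  if (abs(d) > 1e-12 && d < 0) e1 <- -e1
  .unit(e1)
}

#' Per-voxel pennation angles
#'
#' `theta = acos(|d . a| / (||d|| ||a||))` in degrees, folded to `[0, 90]`
#' (antiparallel equals parallel); missing voxels stay missing.
#'
#' @param field a [DirectionField-class].
#' @param apoDir aponeurosis direction (grid-frame components, non-zero).
#' @return 3D array of angles in degrees (NaN = missing).
#' @export
pennationAngles <- function(field, apoDir) {
  a <- .unit(apoDir)
  v <- matrix(field@vectors, ncol = 3)
  nrm <- sqrt(rowSums(v^2))
  if (any(is.finite(nrm) & nrm == 0))
    stop("zero-length vector in field")
  dots <- (v %*% a) / nrm
  array(.folded_angle_deg(dots), dims(field))
}

#' Resampled per-compartment angle summary
#'
#' Uniform random sample of `n` voxel angles without replacement (with
#' replacement, flagged, iff fewer than `n` are available), deterministic
#' given `seed`.
#'
#' @param angles 3D angle array (degrees, NaN = missing).
#' @param mask compartment [MaskVolume-class].
#' @param n resample size (default 5000).
#' @param seed RNG seed.
#' @param compartment optional label stored in the result.
#' @return one-row data.frame: nAvailable, nResampled, withReplacement,
#'   mean, sd, q25, median, q75, seed.
#' @export
compartmentSummary <- function(angles, mask, n = 5000L, seed = 1L,
                               compartment = NA_character_) {
  stopifnot(all(dim(angles) == dims(mask)))
  vals <- angles[mask@data & is.finite(angles)]
  if (!length(vals)) stop("empty support: no angles inside mask")
  withRepl <- length(vals) < n
  old <- globalenv()$.Random.seed
  set.seed(seed)
  smp <- sample(vals, n, replace = withRepl)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  q <- stats::quantile(smp, c(0.25, 0.5, 0.75), names = FALSE)
  data.frame(compartment = compartment, nAvailable = length(vals),
             nResampled = as.integer(n), withReplacement = withRepl,
             mean = mean(smp), sd = stats::sd(smp), q25 = q[1],
             median = q[2], q75 = q[3], seed = as.integer(seed))
}

.support_vectors <- function(field) {
  v <- matrix(field@vectors, ncol = 3)
  v <- v[is.finite(v[, 1]), , drop = FALSE]
  v / sqrt(rowSums(v^2))
}

# orientation-aware mean: sign-align all vectors to the principal
# orientation (eigenvector of the orientation tensor), then normed sum, so
# v and -v average to +-v rather than 0
.mean_direction <- function(V) {
  M <- crossprod(V) / nrow(V)
  ref <- eigen(M, symmetric = TRUE)$vectors[, 1]
  s <- sign(V %*% ref)
  s[s == 0] <- 1
  .unit(colSums(V * as.numeric(s)))
}

#' Pairwise inter-compartment angle statistics for the wire phantom
#'
#' Folded angles between every direction vector of one compartment and
#' every vector of the other (seeded subsampling caps the pair count),
#' their mean absolute error against the true inter-group angle, and the
#' folded angle between the compartments' normed mean directions.
#'
#' @param fieldA,fieldB detected [DirectionField-class] per compartment.
#' @param truth true inter-group angle, degrees.
#' @param maxPairs pair-count cap (default 1e7); beyond it pairs are
#'   subsampled with `seed` and the result flagged.
#' @param seed RNG seed for subsampling.
#' @return A [PhantomAngleStats-class].
#' @export
phantomAngles <- function(fieldA, fieldB, truth, maxPairs = 1e7, seed = 1L) {
  VA <- .support_vectors(fieldA)
  VB <- .support_vectors(fieldB)
  if (!nrow(VA) || !nrow(VB)) stop("empty field")
  nTot <- as.numeric(nrow(VA)) * nrow(VB)
  subsampled <- nTot > maxPairs
  if (!subsampled) {
    ang <- .folded_angle_deg(VA %*% t(VB))
    nPairs <- nTot
  } else {
    old <- globalenv()$.Random.seed
    set.seed(seed)
    iA <- sample.int(nrow(VA), maxPairs, replace = TRUE)
    iB <- sample.int(nrow(VB), maxPairs, replace = TRUE)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    ang <- .folded_angle_deg(rowSums(VA[iA, ] * VB[iB, ]))
    nPairs <- maxPairs
  }
  err <- as.vector(ang) - truth
  mA <- .mean_direction(VA)
  mB <- .mean_direction(VB)
  keep <- if (length(err) > 1e5) {
    # keep a deterministic thinned sample of the distribution for plotting
    as.vector(ang)[seq(1, length(err), length.out = 1e5)]
  } else as.vector(ang)
  new("PhantomAngleStats", angles = keep, mae = mean(abs(err)),
      maeSd = stats::sd(abs(err)), meanRelErrDeg = mean(err),
      meanRelErr = mean(abs(err)) / truth,
      meanDirectionAngle = .folded_angle_deg(sum(mA * mB)),
      truth = truth, nPairs = nPairs, subsampled = subsampled)
}

#' Muscle volume from a segmentation mask
#'
#' Voxel count times voxel volume, in cm^3.
#'
#' @param mask a [MaskVolume-class].
#' @return volume in cm^3.
#' @export
muscleVolume <- function(mask) {
  stopifnot(is(mask, "MaskVolume"))
  sum(mask@data) * prod(spacing(mask)) / 1000
}
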