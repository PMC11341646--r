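# End-to-end detection pipelines: per-compartment direction detection, the
# wire-phantom workflow and the muscle pennation workflow.

.bbox <- function(mask, margin, dims) {
  idx <- which(mask, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - margin, 1L)
  hi <- pmin(apply(idx, 2, max) + margin, dims)
  list(lo = lo, hi = hi)
}

.crop_vol <- function(vol, bb) {
  d <- vol@data[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3],
                drop = FALSE]
  org <- as.numeric(voxelToWorld(vol, matrix(bb$lo - 1L, 1)))
  if (is(vol, "MaskVolume"))
    MaskVolume(d, spacing = spacing(vol), origin = org,
               axes = gridAxes(vol))
  else ScanVolume(d, spacing = spacing(vol), origin = org,
                  axes = gridAxes(vol), scaleFactor = vol@scaleFactor)
}

#' Detect fascicle directions within one compartment
#'
#' Runs the full detection cascade: aponeurosis zeroing and compartment
#' masking, slice-wise vessel enhancement, re-stitching, 3D
#' Gaussian/Hessian eigenanalysis, 10%-of-maximum binarization with mask
#' shrinking, anisotropic length scaling with 50%-length pruning,
#' endpoint removal by neighbour count, and penalized least-squares
#' smoothing of the surviving vectors (re-normalized to unit length). The
#' computation is cropped to the compartment bounding box (plus a filter
#' margin) and re-embedded.
#'
#' @param vol reconstructed [ScanVolume-class].
#' @param compartmentMask compartment [MaskVolume-class].
#' @param apoMask optional aponeurosis [MaskVolume-class].
#' @param config a [PipelineConfig-class].
#' @param cropMargin bounding-box margin in voxels.
#' @return list with `field` (support-only unit [DirectionField-class]) and
#'   `degenerate` (logical array on the full grid).
#' @export
detectDirections <- function(vol, compartmentMask, apoMask = NULL,
                             config = PipelineConfig(), cropMargin = 16L) {
  .stopifnot_same_geometry(vol, compartmentMask, "volume and mask")
  if (!any(compartmentMask@data)) stop("empty mask")
  d <- dims(vol)
  bb <- .bbox(compartmentMask@data, cropMargin, d)
  cvol <- .crop_vol(vol, bb)
  cmask <- .crop_vol(compartmentMask, bb)
  capo <- if (!is.null(apoMask)) .crop_vol(apoMask, bb) else NULL
  mvef <- applyMVEF(cvol, cmask, capo, config@frangi)
  dirs <- directionField(mvef, hessianSigma = config@prune@hessianSigma,
                         mask = cmask@data)
  fmask <- fascicleMask(mvef, cmask, config@prune)
  field <- scaleAndPruneLengths(dirs$field, fmask,
                                config@prune@lengthFraction)
  field <- pruneEndpoints(field, config@prune@minNeighbors)
  sup <- supportMask(field)
  if (!any(sup)) stop("no directions survived pruning")
  sm <- smoothField(field, s = config@smooth@sMain,
                    robust = config@smooth@robust,
                    maxIter = config@smooth@maxIter, tol = config@smooth@tol)
  v <- matrix(sm@vectors, ncol = 3)
  v[!as.vector(sup), ] <- NaN
  nrm <- sqrt(rowSums(v^2))
  v <- v / nrm
  # re-embed the cropped field into the full grid
  full <- array(NaN, c(d, 3))
  degen <- array(FALSE, d)
  rng <- lapply(1:3, function(i) bb$lo[i]:bb$hi[i])
  full[rng[[1]], rng[[2]], rng[[3]], ] <- array(v, c(dims(cvol), 3))
  degen[rng[[1]], rng[[2]], rng[[3]]] <- dirs$degenerate
  list(field = DirectionField(full, spacing = spacing(vol),
                              origin = origin(vol), axes = gridAxes(vol)),
       degenerate = degen)
}

#' Wire-phantom detection workflow
#'
#' Detects directions in both wire compartments (no mask shrinking, "xz"
#' slice plane) and computes the pairwise angle statistics against the
#' known inter-group angle.
#'
#' @param vol phantom [ScanVolume-class].
#' @param maskA,maskB compartment masks.
#' @param truth true inter-group angle, degrees.
#' @param config a [PipelineConfig-class] (default [phantomConfig()]).
#' @param maxPairs pairwise-angle cap, see [phantomAngles()].
#' @return list with `fieldA`, `fieldB` and `stats`
#'   ([PhantomAngleStats-class]).
#' @export
phantomPipeline <- function(vol, maskA, maskB, truth,
                            config = phantomConfig(), maxPairs = 1e7) {
  a <- detectDirections(vol, maskA, config = config)
  b <- detectDirections(vol, maskB, config = config)
  stats <- phantomAngles(a$field, b$field, truth, maxPairs = maxPairs,
                         seed = config@seed)
  list(fieldA = a$field, fieldB = b$field, stats = stats)
}

#' Muscle pennation workflow
#'
#' Rotates the volume and masks into the muscle coordinate system (PCA of
#' the whole-muscle mask), detects directions per compartment, fills each
#' compartment by interpolation/extrapolation, and summarizes pennation
#' angles against the aponeurosis principal axis with seeded resampling.
#'
#' @param vol reconstructed [ScanVolume-class].
#' @param muscleMask whole-muscle mask.
#' @param compartments named list of compartment [MaskVolume-class]s.
#' @param apoMask aponeurosis mask.
#' @param config a [PipelineConfig-class].
#' @param rotate align the volume with the muscle frame first (default
#'   TRUE).
#' @return A [PennationResult-class]; the angle volume and summaries are in
#'   the (rotated) muscle frame.
#' @export
musclePipeline <- function(vol, muscleMask, compartments, apoMask,
                           config = PipelineConfig(), rotate = TRUE) {
  if (rotate) {
    frame <- muscleFrame(muscleMask)
    vol <- rotateVolume(vol, frame)
    muscleMask <- rotateVolume(muscleMask, frame)
    compartments <- lapply(compartments, rotateVolume, frame = frame)
    apoMask <- rotateVolume(apoMask, frame)
  }
  apoDir <- aponeurosisDirection(apoMask)
  d <- dims(vol)
  angleVol <- array(NaN, d)
  summaries <- NULL
  for (nm in names(compartments)) {
    det <- detectDirections(vol, compartments[[nm]], apoMask = apoMask,
                            config = config)
    filled <- fillMuscle(det$field, compartments[[nm]], config@smooth)
    ang <- pennationAngles(filled, apoDir)
    inC <- compartments[[nm]]@data
    angleVol[inC] <- ang[inC]
    summaries <- rbind(summaries,
                       compartmentSummary(ang, compartments[[nm]],
                                          n = config@resampleN,
                                          seed = config@seed,
                                          compartment = nm))
  }
  new("PennationResult", angleVolume = angleVol, summaries = summaries,
      apoDirection = apoDir, spacing = spacing(vol), origin = origin(vol),
      axes = gridAxes(vol))
}
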