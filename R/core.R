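# Constructors, accessors, show methods and the index<->world affine.

#' Create a ScanVolume
#'
#' @param data 3D numeric array of intensities.
#' @param spacing voxel size (mm), length 3.
#' @param origin world position (mm) of voxel (0,0,0).
#' @param axes 3x3 orthonormal matrix of grid axis directions.
#' @param scaleFactor intensity scale factor applied on load.
#' @return A [ScanVolume-class].
#' @export
ScanVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       axes = diag(3), scaleFactor = 1) {
  storage.mode(data) <- "double"
  new("ScanVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin), axes = axes,
      scaleFactor = as.numeric(scaleFactor))
}

#' Create a MaskVolume
#'
#' @param data 3D logical (or 0/1) array.
#' @inheritParams ScanVolume
#' @return A [MaskVolume-class].
#' @export
MaskVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       axes = diag(3)) {
  if (!is.logical(data)) {
    if (!all(data %in% c(0, 1)))
      stop("mask data must be logical or contain only 0/1")
    data <- array(data != 0, dim(data))
  }
  new("MaskVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin), axes = axes)
}

#' Create a DirectionField
#'
#' @param vectors 4D array `c(nx, ny, nz, 3)`; missing voxels all-NaN.
#' @inheritParams ScanVolume
#' @return A [DirectionField-class].
#' @export
DirectionField <- function(vectors, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                           axes = diag(3)) {
  storage.mode(vectors) <- "double"
  new("DirectionField", vectors = vectors, spacing = as.numeric(spacing),
      origin = as.numeric(origin), axes = axes)
}

#' @export
FrameStack <- function(frames, pixelSpacing, timestamps) {
  frames <- lapply(frames, function(f) { storage.mode(f) <- "double"; f })
  new("FrameStack", frames = frames, pixelSpacing = as.numeric(pixelSpacing),
      timestamps = as.numeric(timestamps))
}

#' @export
PoseSequence <- function(rotations, translations, timestamps) {
  new("PoseSequence", rotations = rotations,
      translations = as.matrix(translations),
      timestamps = as.numeric(timestamps))
}

#' @export
FrangiParams <- function(sigma = 2, beta = 0.5, c = 15, plane = "yz")
  new("FrangiParams", sigma = sigma, beta = beta, c = c, plane = plane)

#' @export
PruneParams <- function(hessianSigma = 2, binarizeFraction = 0.10,
                        shrinkVoxels = 10L, lengthFraction = 0.50,
                        minNeighbors = 18L)
  new("PruneParams", hessianSigma = hessianSigma,
      binarizeFraction = binarizeFraction,
      shrinkVoxels = as.integer(shrinkVoxels),
      lengthFraction = lengthFraction,
      minNeighbors = as.integer(minNeighbors))

#' @export
SmoothParams <- function(sMain = 35, sExtrap = 0.5, robust = FALSE,
                         maxIter = 100L, tol = 1e-3)
  new("SmoothParams", sMain = sMain, sExtrap = sExtrap, robust = robust,
      maxIter = as.integer(maxIter), tol = tol)

#' Pipeline configuration
#'
#' `PipelineConfig()` returns the muscle defaults (Frangi sigma 2, yz slice
#' plane, 10 erosion iterations); `phantomConfig()` the phantom defaults
#' (sigma 3.5, xz plane, no erosion).
#'
#' @param frangi,prune,smooth parameter objects.
#' @param resampleN angles resampled per compartment (default 5000).
#' @param seed RNG seed for seeded resampling steps.
#' @return A [PipelineConfig-class].
#' @export
PipelineConfig <- function(frangi = FrangiParams(), prune = PruneParams(),
                           smooth = SmoothParams(), resampleN = 5000L,
                           seed = 1L)
  new("PipelineConfig", frangi = frangi, prune = prune, smooth = smooth,
      resampleN = as.integer(resampleN), seed = as.integer(seed))

#' @rdname PipelineConfig
#' @export
phantomConfig <- function(seed = 1L)
  PipelineConfig(frangi = FrangiParams(sigma = 3.5, plane = "xz"),
                 prune = PruneParams(shrinkVoxels = 0L), seed = seed)

#' @export
SpeckleParams <- function(psfSigma = c(0.2, 0.4), multSigma = 0.08,
                          addSigma = 2)
  new("SpeckleParams", psfSigma = as.numeric(psfSigma),
      multSigma = multSigma, addSigma = addSigma)

#' Wire-phantom specification (see [WirePhantomSpec-class])
#'
#' @param wallSeparation captured wire length, mm.
#' @param holePitch wall hole grid pitch, mm.
#' @param rowsA,colsA group-A array layout.
#' @param nB number of group-B wires.
#' @param wireDiameter mm.
#' @param interGroupAngle degrees.
#' @param intensities named (background, wire, water).
#' @param spacing voxel size, mm.
#' @param noise a [SpeckleParams-class].
#' @param seed generator seed.
#' @export
WirePhantomSpec <- function(wallSeparation = 24, holePitch = 2.5, rowsA = 3L,
                            colsA = 6L, nB = 2L, wireDiameter = 0.1,
                            interGroupAngle = 10.78,
                            intensities = c(background = 2, wire = 255,
                                            water = 4),
                            spacing = c(0.14, 0.14, 0.37),
                            noise = SpeckleParams(), seed = 1L)
  new("WirePhantomSpec", wallSeparation = wallSeparation,
      holePitch = holePitch, rowsA = as.integer(rowsA),
      colsA = as.integer(colsA), nB = as.integer(nB),
      wireDiameter = wireDiameter, interGroupAngle = interGroupAngle,
      intensities = intensities, spacing = as.numeric(spacing), noise = noise,
      seed = as.integer(seed))

#' Pennate-muscle specification (see [PennateMuscleSpec-class])
#'
#' @param semiAxes envelope semi-axes, mm.
#' @param superellipseExp cross-section superellipse exponent.
#' @param apoThickness aponeurosis thickness, mm.
#' @param pennationSuperficial,pennationDeep degrees.
#' @param fasciclePitch,lineWidth perimysium line pitch/width, mm.
#' @param intensities named (background, muscle, line, aponeurosis).
#' @param spacing voxel size, mm.
#' @param noise a [SpeckleParams-class].
#' @param seed generator seed.
#' @export
PennateMuscleSpec <- function(semiAxes = c(9, 6.5, 19), superellipseExp = 2.5,
                              apoThickness = 0.8, pennationSuperficial = 5,
                              pennationDeep = 10, fasciclePitch = 2.4,
                              lineWidth = 0.6,
                              intensities = c(background = 5, muscle = 40,
                                              line = 220, aponeurosis = 255),
                              spacing = c(0.17, 0.17, 0.66),
                              noise = SpeckleParams(), seed = 1L)
  new("PennateMuscleSpec", semiAxes = as.numeric(semiAxes),
      superellipseExp = superellipseExp, apoThickness = apoThickness,
      pennationSuperficial = pennationSuperficial,
      pennationDeep = pennationDeep, fasciclePitch = fasciclePitch,
      lineWidth = lineWidth, intensities = intensities,
      spacing = as.numeric(spacing), noise = noise, seed = as.integer(seed))

# ---- accessors ----

#' @describeIn ScanVolume intensity array.
#' @export
setMethod("volData", "ScanVolume", function(x) x@data)

#' @export
setMethod("maskData", "MaskVolume", function(x) x@data)

#' @export
setMethod("spacing", "VoxelGrid", function(x) x@spacing)

#' @export
setMethod("spacing", "VolumeGrid", function(x) x@spacing)

#' @export
setMethod("origin", "VoxelGrid", function(x) x@origin)

#' @export
setMethod("origin", "VolumeGrid", function(x) x@origin)

#' @export
setMethod("gridAxes", "VoxelGrid", function(x) x@axes)

#' @export
setMethod("gridAxes", "VolumeGrid", function(x) x@axes)

#' @export
setMethod("dims", "ScanVolume", function(x) dim(x@data))

#' @export
setMethod("dims", "MaskVolume", function(x) dim(x@data))

#' @export
setMethod("dims", "DirectionField", function(x) dim(x@vectors)[1:3])

#' @export
setMethod("dims", "VolumeGrid", function(x) x@dims)

#' @export
setMethod("fieldVectors", "DirectionField", function(x) x@vectors)

#' @describeIn DirectionField logical array of non-missing voxels.
#' @export
setMethod("supportMask", "DirectionField", function(x)
  array(is.finite(x@vectors[, , , 1]), dim(x@vectors)[1:3]))

#' @export
setMethod("nSupport", "DirectionField", function(x) sum(supportMask(x)))

# index <-> world: world = origin + axes %*% (index * spacing), index 0-based
#' @describeIn VoxelGrid world coordinates (mm, Nx3) of 0-based voxel
#'   indices (Nx3).
#' @param x grid-carrying object.
#' @param index Nx3 matrix of 0-based voxel indices.
#' @export
setMethod("voxelToWorld", "VoxelGrid", function(x, index) {
  index <- matrix(index, ncol = 3)
  v <- sweep(index, 2, x@spacing, "*")
  sweep(v %*% t(x@axes), 2, x@origin, "+")
})

#' @describeIn VoxelGrid continuous 0-based voxel indices of world
#'   coordinates (mm, Nx3).
#' @param world Nx3 matrix of world coordinates (mm).
#' @export
setMethod("worldToVoxel", "VoxelGrid", function(x, world) {
  world <- matrix(world, ncol = 3)
  v <- sweep(world, 2, x@origin, "-") %*% x@axes
  sweep(v, 2, x@spacing, "/")
})

.same_geometry <- function(a, b, tol = 1e-9) {
  all(dims(a) == dims(b)) &&
    max(abs(spacing(a) - spacing(b))) <= tol &&
    max(abs(origin(a) - origin(b))) <= tol &&
    max(abs(gridAxes(a) - gridAxes(b))) <= tol
}

.stopifnot_same_geometry <- function(a, b, what = "objects") {
  if (!.same_geometry(a, b))
    stop(what, " must share the same grid geometry")
  invisible(TRUE)
}

# ---- show ----

setMethod("show", "ScanVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("ScanVolume %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  cat(sprintf("  intensity range [%.3g, %.3g]\n", min(object@data),
              max(object@data)))
})

setMethod("show", "MaskVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("MaskVolume %d x %d x %d voxels, %d inside (%.1f%%)\n",
              d[1], d[2], d[3], sum(object@data),
              100 * mean(object@data)))
})

setMethod("show", "DirectionField", function(object) {
  d <- dim(object@vectors)
  n <- sum(is.finite(object@vectors[, , , 1]))
  cat(sprintf("DirectionField %d x %d x %d voxels, %d with directions (%.1f%%)\n",
              d[1], d[2], d[3], n, 100 * n / prod(d[1:3])))
})

setMethod("show", "PhantomAngleStats", function(object) {
  cat(sprintf("PhantomAngleStats: truth %.2f deg, %g pairs%s\n", object@truth,
              object@nPairs, if (object@subsampled) " (subsampled)" else ""))
  cat(sprintf("  MAE %.3f +- %.3f deg; mean-direction angle %.3f deg\n",
              object@mae, object@maeSd, object@meanDirectionAngle))
})

setMethod("show", "PennationResult", function(object) {
  cat("PennationResult\n")
  print(object@summaries)
})
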