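# S4 classes for volumes, masks, direction fields, acquisition containers
# and parameter sets.

.check_axes <- function(axes, tol = 1e-9) {
  if (!is.matrix(axes) || any(dim(axes) != c(3L, 3L)))
    return("axes must be a 3x3 matrix")
  if (any(!is.finite(axes))) return("axes must be finite")
  if (max(abs(crossprod(axes) - diag(3))) > tol)
    return("axes must be orthonormal (column-wise) within 1e-9")
  NULL
}

.check_grid <- function(object) {
  msg <- character(0)
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive finite values (mm/voxel)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be a finite 3-vector (mm)")
  msg <- c(msg, .check_axes(object@axes))
  if (length(msg)) msg else TRUE
}

#' Virtual base class carrying voxel-grid geometry
#'
#' Geometry follows one affine everywhere: the world coordinate (mm) of the
#' 0-based voxel index \eqn{(i,j,k)} is
#' \eqn{origin + axes \cdot (index \circ spacing)}, with the first index
#' varying fastest in storage.
#'
#' @slot spacing voxel size in mm along each grid axis (positive).
#' @slot origin world coordinate (mm) of voxel (0,0,0).
#' @slot axes 3x3 orthonormal matrix; columns are the world directions of the
#'   grid axes.
#' @export
setClass("VoxelGrid",
         representation("VIRTUAL", spacing = "numeric", origin = "numeric",
                        axes = "matrix"),
         prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0), axes = diag(3)),
         validity = .check_grid)

#' 3D scalar intensity volume
#'
#' The central image container: a 3D grid of intensities on the 0-255 scale
#' (readers rescale wider-typed sources and record the factor in
#' `scaleFactor`, so the original intensities are `data / scaleFactor`).
#'
#' @slot data 3D numeric array of finite intensities.
#' @slot scaleFactor factor applied to the source intensities on load
#'   (1 = unscaled).
#' @export
setClass("ScanVolume", contains = "VoxelGrid",
         representation(data = "array", scaleFactor = "numeric"),
         prototype(data = array(0, c(1, 1, 1)), scaleFactor = 1),
         validity = function(object) {
           if (length(dim(object@data)) != 3L)
             return("data must be a 3D array")
           if (any(!is.finite(object@data)))
             return("data must be finite")
           if (length(object@scaleFactor) != 1L ||
               !is.finite(object@scaleFactor) || object@scaleFactor <= 0)
             return("scaleFactor must be a single positive number")
           TRUE
         })

#' Binary mask on a voxel grid
#'
#' @slot data 3D logical array; TRUE marks voxels inside the mask.
#' @export
setClass("MaskVolume", contains = "VoxelGrid",
         representation(data = "array"),
         prototype(data = array(FALSE, c(1, 1, 1))),
         validity = function(object) {
           if (length(dim(object@data)) != 3L)
             return("data must be a 3D array")
           if (!is.logical(object@data) || anyNA(object@data))
             return("mask data must be logical without NA")
           TRUE
         })

#' Per-voxel 3D direction field
#'
#' One 3-component vector per voxel; missing voxels are marked by NaN in all
#' three components (the missing sentinel is distinct from the zero vector,
#' which is a legal direction only before normalization).
#'
#' @slot vectors 4D numeric array, dims `c(nx, ny, nz, 3)`.
#' @export
setClass("DirectionField", contains = "VoxelGrid",
         representation(vectors = "array"),
         prototype(vectors = array(NaN, c(1, 1, 1, 3))),
         validity = function(object) {
           d <- dim(object@vectors)
           if (length(d) != 4L || d[4] != 3L)
             return("vectors must be a 4D array with last dimension 3")
           v <- matrix(object@vectors, ncol = 3)
           fin <- rowSums(is.finite(v))
           if (any(fin != 0L & fin != 3L))
             return("each voxel must be fully finite or fully missing (NaN)")
           TRUE
         })

#' Timed stack of 2D B-mode frames
#'
#' @slot frames list of equal-sized numeric matrices (intensities).
#' @slot pixelSpacing in-plane pixel size (mm), length 2.
#' @slot timestamps acquisition times in seconds, strictly increasing.
#' @export
setClass("FrameStack",
         representation(frames = "list", pixelSpacing = "numeric",
                        timestamps = "numeric"),
         validity = function(object) {
           if (!length(object@frames)) return("frames must be non-empty")
           d <- dim(object@frames[[1]])
           ok <- vapply(object@frames, function(f)
             is.matrix(f) && identical(dim(f), d), logical(1))
           if (!all(ok)) return("all frames must share the same dimensions")
           if (length(object@pixelSpacing) != 2L ||
               any(object@pixelSpacing <= 0))
             return("pixelSpacing must be 2 positive values")
           if (length(object@timestamps) != length(object@frames))
             return("one timestamp per frame required")
           if (any(diff(object@timestamps) <= 0))
             return("timestamps must be strictly increasing")
           TRUE
         })

#' Sequence of rigid tracker poses
#'
#' Each pose maps in-plane image coordinates (mm) to device coordinates (mm):
#' world = R p + t.
#'
#' @slot rotations 3x3xN array of orthonormal rotation matrices.
#' @slot translations Nx3 matrix of translations (mm).
#' @slot timestamps seconds, strictly increasing.
#' @export
setClass("PoseSequence",
         representation(rotations = "array", translations = "matrix",
                        timestamps = "numeric"),
         validity = function(object) {
           d <- dim(object@rotations)
           if (length(d) != 3L || d[1] != 3L || d[2] != 3L)
             return("rotations must be a 3x3xN array")
           n <- d[3]
           for (i in seq_len(n)) {
             R <- object@rotations[, , i]
             if (max(abs(crossprod(R) - diag(3))) > 1e-9)
               return(sprintf("rotation %d not orthonormal within 1e-9", i))
           }
           if (nrow(object@translations) != n ||
               ncol(object@translations) != 3L)
             return("translations must be Nx3")
           if (length(object@timestamps) != n)
             return("one timestamp per pose required")
           if (n > 1 && any(diff(object@timestamps) <= 0))
             return("timestamps must be strictly increasing")
           TRUE
         })

#' Reconstruction grid defined by PCA of frame corners
#'
#' @slot origin world coordinate (mm) of voxel (0,0,0).
#' @slot axes 3x3 orthonormal; columns = principal axes of the corner cloud.
#' @slot spacing voxel size (mm).
#' @slot dims integer voxel counts per axis.
#' @export
setClass("VolumeGrid",
         representation(origin = "numeric", axes = "matrix",
                        spacing = "numeric", dims = "integer"),
         validity = function(object) {
           msg <- .check_axes(object@axes)
           if (!is.null(msg)) return(msg)
           if (any(object@spacing <= 0)) return("spacing must be positive")
           if (length(object@dims) != 3L || any(object@dims < 1L))
             return("dims must be 3 integers >= 1")
           TRUE
         })

#' Muscle-aligned coordinate frame from mask PCA
#'
#' @slot rotation 3x3 orthonormal, det +1; columns are the muscle principal
#'   axes expressed in volume world coordinates, ordered by decreasing
#'   variance.
#' @slot centroid mask centroid, world mm.
#' @export
setClass("MuscleFrame",
         representation(rotation = "matrix", centroid = "numeric"),
         validity = function(object) {
           msg <- .check_axes(object@rotation)
           if (!is.null(msg)) return(msg)
           if (abs(det(object@rotation) - 1) > 1e-6)
             return("rotation must be right-handed (det +1)")
           if (length(object@centroid) != 3L) return("centroid must be length 3")
           TRUE
         })

# ---- parameter classes ----

#' Frangi vesselness parameters (slice-wise filter)
#'
#' Defaults follow the filter calibration used throughout: Gaussian scale
#' sigma in pixels of the slice grid (2 for muscle data, 3.5 for phantom
#' data), blob-suppression beta = 0.5, second-order structure sensitivity
#' c = 15 on 0-255 intensities, bright-on-dark polarity, and the sagittal
#' slice plane ("yz" for muscle, "xz" for phantom volumes).
#'
#' @slot sigma Gaussian scale in slice pixels; a vector enables the
#'   multi-scale variant (pointwise maximum over scales).
#' @slot beta blob-ness sensitivity.
#' @slot c structure-ness sensitivity (intensity units).
#' @slot plane slice plane, "yz" or "xz".
#' @export
setClass("FrangiParams",
         representation(sigma = "numeric", beta = "numeric", c = "numeric",
                        plane = "character"),
         prototype(sigma = 2, beta = 0.5, c = 15, plane = "yz"),
         validity = function(object) {
           if (!length(object@sigma) || any(object@sigma <= 0))
             return("sigma must be > 0")
           if (object@beta <= 0 || object@c <= 0)
             return("beta and c must be > 0")
           if (!object@plane %in% c("yz", "xz"))
             return("plane must be 'yz' or 'xz'")
           TRUE
         })

#' Pruning-cascade parameters
#'
#' @slot hessianSigma 3D Gaussian scale (voxels) before the Hessian.
#' @slot binarizeFraction keep voxels >= this fraction of the maximum
#'   filtered value (default 0.10).
#' @slot shrinkVoxels iterations of 6-connected mask erosion (default 10 for
#'   muscle compartments; use 0 for phantom data).
#' @slot lengthFraction remove spacing-scaled vectors shorter than this
#'   fraction of the maximum length (default 0.50).
#' @slot minNeighbors voxels with fewer non-empty 26-neighbours are removed
#'   (default 18; exactly 18 survives).
#' @export
setClass("PruneParams",
         representation(hessianSigma = "numeric", binarizeFraction = "numeric",
                        shrinkVoxels = "integer", lengthFraction = "numeric",
                        minNeighbors = "integer"),
         prototype(hessianSigma = 2, binarizeFraction = 0.10,
                   shrinkVoxels = 10L, lengthFraction = 0.50,
                   minNeighbors = 18L),
         validity = function(object) {
           if (object@hessianSigma <= 0) return("hessianSigma must be > 0")
           if (object@binarizeFraction <= 0 || object@binarizeFraction >= 1)
             return("binarizeFraction must be in (0,1)")
           if (object@lengthFraction <= 0 || object@lengthFraction >= 1)
             return("lengthFraction must be in (0,1)")
           if (object@shrinkVoxels < 0L) return("shrinkVoxels must be >= 0")
           if (object@minNeighbors < 0L || object@minNeighbors > 26L)
             return("minNeighbors must be in [0,26]")
           TRUE
         })

#' Penalized least-squares smoother parameters
#'
#' @slot sMain smoothing parameter for the detected field (default 35).
#' @slot sExtrap smoothing parameter for whole-muscle extrapolation
#'   (default 0.5).
#' @slot robust enable bisquare reweighting of residuals.
#' @slot maxIter missing-value iteration cap.
#' @slot tol relative-change convergence tolerance.
#' @export
setClass("SmoothParams",
         representation(sMain = "numeric", sExtrap = "numeric",
                        robust = "logical", maxIter = "integer",
                        tol = "numeric"),
         prototype(sMain = 35, sExtrap = 0.5, robust = FALSE, maxIter = 100L,
                   tol = 1e-3),
         validity = function(object) {
           if (object@sMain < 0 || object@sExtrap < 0)
             return("smoothing parameters must be >= 0")
           if (object@maxIter < 1L) return("maxIter must be >= 1")
           if (object@tol <= 0) return("tol must be > 0")
           TRUE
         })

#' Full pipeline configuration
#'
#' @slot frangi [FrangiParams-class] for the slice-wise vesselness stage.
#' @slot prune [PruneParams-class] for the pruning cascade.
#' @slot smooth [SmoothParams-class] for the vector-field smoother.
#' @slot resampleN angles resampled per compartment in summaries
#'   (default 5000).
#' @slot seed RNG seed for resampling/subsampling steps.
#' @export
setClass("PipelineConfig",
         representation(frangi = "FrangiParams", prune = "PruneParams",
                        smooth = "SmoothParams", resampleN = "integer",
                        seed = "integer"),
         prototype(resampleN = 5000L, seed = 1L),
         validity = function(object) {
           if (object@resampleN < 1L) return("resampleN must be >= 1")
           TRUE
         })

# ---- synthetic-scene classes ----

#' Ultrasound speckle / point-spread parameters
#'
#' Speckle is modelled as an anisotropic Gaussian point-spread blur followed
#' by multiplicative Gaussian noise (a log-compressed-speckle surrogate) and
#' additive electronic noise, clipped to 0-255.
#'
#' @slot psfSigma (axial, lateral) PSF standard deviation in mm; the lateral
#'   value is applied in both lateral directions (in-plane and elevational).
#' @slot multSigma standard deviation of the multiplicative noise.
#' @slot addSigma standard deviation of the additive noise (intensity units).
#' @export
setClass("SpeckleParams",
         representation(psfSigma = "numeric", multSigma = "numeric",
                        addSigma = "numeric"),
         prototype(psfSigma = c(0.2, 0.4), multSigma = 0.08, addSigma = 2),
         validity = function(object) {
           if (length(object@psfSigma) != 2L || any(object@psfSigma < 0))
             return("psfSigma must be 2 non-negative values (axial, lateral)")
           if (object@multSigma < 0 || object@addSigma < 0)
             return("noise sigmas must be >= 0")
           TRUE
         })

#' Synthetic wire-phantom specification
#'
#' Emulates a fascicle phantom: two groups of thin wires (a 3-row x 6-column
#' array and a 2-wire pair, holes 2.5 mm apart) spanned between parallel
#' walls at a known inter-group angle, immersed in water and imaged at the
#' phantom reconstruction spacing 0.14 x 0.14 x 0.37 mm.
#'
#' @slot wallSeparation wire length captured in the volume, mm.
#' @slot holePitch spacing of the wall hole grid, mm (2.5).
#' @slot rowsA,colsA layout of wire group A (3 x 6).
#' @slot nB wires in group B (2, side by side).
#' @slot wireDiameter mm (0.1).
#' @slot interGroupAngle known angle between the groups, degrees (10.78).
#' @slot intensities named (background, wire, water) on 0-255.
#' @slot spacing voxel size, mm.
#' @slot noise [SpeckleParams-class].
#' @slot seed generator seed.
#' @export
setClass("WirePhantomSpec",
         representation(wallSeparation = "numeric", holePitch = "numeric",
                        rowsA = "integer", colsA = "integer", nB = "integer",
                        wireDiameter = "numeric", interGroupAngle = "numeric",
                        intensities = "numeric", spacing = "numeric",
                        noise = "SpeckleParams", seed = "integer"),
         prototype(wallSeparation = 24, holePitch = 2.5, rowsA = 3L,
                   colsA = 6L, nB = 2L, wireDiameter = 0.1,
                   interGroupAngle = 10.78,
                   intensities = c(background = 2, wire = 255, water = 4),
                   spacing = c(0.14, 0.14, 0.37), seed = 1L),
         validity = function(object) {
           if (object@interGroupAngle <= 0 || object@interGroupAngle >= 90)
             return("interGroupAngle must be in (0, 90) degrees")
           if (object@holePitch <= object@wireDiameter)
             return("holePitch must exceed wireDiameter")
           if (object@rowsA < 1L || object@colsA < 1L || object@nB < 1L)
             return("both wire groups must be non-empty")
           if (length(object@spacing) != 3L || any(object@spacing <= 0))
             return("spacing must be 3 positive values")
           TRUE
         })

#' Synthetic two-compartment pennate muscle specification
#'
#' A superellipsoid muscle envelope split by a bright central aponeurosis
#' sheet; each compartment contains parallel bright perimysium lines at its
#' programmed pennation angle to the aponeurosis direction, at the muscle
#' reconstruction spacing 0.17 x 0.17 x 0.66 mm.
#'
#' @slot semiAxes envelope semi-axes (mm), long axis along z.
#' @slot superellipseExp superellipse exponent of the cross-section (2 =
#'   ellipse).
#' @slot apoThickness aponeurosis sheet thickness, mm.
#' @slot pennationSuperficial,pennationDeep programmed pennation angles,
#'   degrees in `[0, 45]`.
#' @slot fasciclePitch distance between bright perimysium lines, mm.
#' @slot lineWidth perimysium line width, mm.
#' @slot intensities named (background, muscle, line, aponeurosis) on 0-255.
#' @slot spacing voxel size, mm.
#' @slot noise [SpeckleParams-class].
#' @slot seed generator seed.
#' @export
setClass("PennateMuscleSpec",
         representation(semiAxes = "numeric", superellipseExp = "numeric",
                        apoThickness = "numeric",
                        pennationSuperficial = "numeric",
                        pennationDeep = "numeric", fasciclePitch = "numeric",
                        lineWidth = "numeric", intensities = "numeric",
                        spacing = "numeric", noise = "SpeckleParams",
                        seed = "integer"),
         prototype(semiAxes = c(9, 6.5, 19), superellipseExp = 2.5,
                   apoThickness = 0.8, pennationSuperficial = 5,
                   pennationDeep = 10, fasciclePitch = 2.4, lineWidth = 0.6,
                   intensities = c(background = 5, muscle = 40, line = 220,
                                   aponeurosis = 255),
                   spacing = c(0.17, 0.17, 0.66), seed = 1L),
         validity = function(object) {
           if (any(c(object@pennationSuperficial, object@pennationDeep) < 0) ||
               any(c(object@pennationSuperficial, object@pennationDeep) > 45))
             return("pennation angles must be in [0, 45] degrees")
           if (object@fasciclePitch <= object@lineWidth)
             return("fasciclePitch must exceed lineWidth")
           if (length(object@semiAxes) != 3L || any(object@semiAxes <= 0))
             return("semiAxes must be 3 positive values")
           TRUE
         })

#' Ground truth of a synthetic scene
#'
#' @slot directions named list of unit 3-vectors (true direction per
#'   compartment).
#' @slot trueAngle known inter-group angle (phantom) in degrees, or NA.
#' @slot angleMap per-voxel true angle (degrees) to the aponeurosis
#'   direction, NaN outside, or NULL-dims placeholder.
#' @slot masks named list of [MaskVolume-class] (compartments, whole,
#'   aponeurosis as applicable).
#' @slot apoDirection true aponeurosis direction (unit) or NA.
#' @export
setClass("GroundTruth",
         representation(directions = "list", trueAngle = "numeric",
                        angleMap = "array", masks = "list",
                        apoDirection = "numeric"),
         prototype(trueAngle = NA_real_, angleMap = array(NaN, c(1, 1, 1)),
                   apoDirection = c(NA_real_, NA_real_, NA_real_)),
         validity = function(object) {
           for (d in object@directions) {
             if (length(d) != 3L || abs(sqrt(sum(d^2)) - 1) > 1e-9)
               return("ground-truth directions must be unit 3-vectors")
           }
           TRUE
         })

#' Pennation-angle result
#'
#' @slot angleVolume per-voxel pennation angle (degrees, NaN = missing) as a
#'   [ScanVolume-class]-geometry array.
#' @slot summaries one row per compartment: n available, n resampled, mean,
#'   sd, quantiles, replacement flag, seed.
#' @slot apoDirection unit aponeurosis direction used.
#' @export
setClass("PennationResult",
         representation(angleVolume = "array", summaries = "data.frame",
                        apoDirection = "numeric", spacing = "numeric",
                        origin = "numeric", axes = "matrix"))

#' Wire-phantom angle statistics
#'
#' @slot angles sampled pairwise inter-compartment angles, degrees.
#' @slot mae mean absolute error vs the true angle, degrees.
#' @slot maeSd standard deviation of the absolute errors, degrees.
#' @slot meanRelErrDeg mean signed deviation (angle - truth), degrees.
#' @slot meanRelErr dimensionless mean(|angle - truth|) / truth.
#' @slot meanDirectionAngle folded angle between the compartments' normed
#'   mean directions, degrees.
#' @slot truth the true inter-group angle, degrees.
#' @slot nPairs number of pairwise angles evaluated.
#' @slot subsampled TRUE if the pair set was capped and seeded-subsampled.
#' @export
setClass("PhantomAngleStats",
         representation(angles = "numeric", mae = "numeric", maeSd = "numeric",
                        meanRelErrDeg = "numeric", meanRelErr = "numeric",
                        meanDirectionAngle = "numeric", truth = "numeric",
                        nPairs = "numeric", subsampled = "logical"))
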