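#' @include AllClasses.R
NULL

#' @export
setGeneric("volData", function(x) standardGeneric("volData"))

#' @export
setGeneric("maskData", function(x) standardGeneric("maskData"))

#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' @export
setGeneric("gridAxes", function(x) standardGeneric("gridAxes"))

#' @export
setGeneric("dims", function(x) standardGeneric("dims"))

#' @export
setGeneric("fieldVectors", function(x) standardGeneric("fieldVectors"))

#' @export
setGeneric("supportMask", function(x) standardGeneric("supportMask"))

#' @export
setGeneric("nSupport", function(x) standardGeneric("nSupport"))

#' @export
setGeneric("voxelToWorld", function(x, index) standardGeneric("voxelToWorld"))

#' @export
setGeneric("worldToVoxel", function(x, world) standardGeneric("worldToVoxel"))
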