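# On-disk formats: MetaImage (.mha, local uncompressed), NIfTI via RNifti,
# TIFF slice stacks with a spacing sidecar, legacy-VTK vector-field export,
# YAML pipeline configuration.

.MHA_TYPES <- list(
  MET_UCHAR  = list(what = "integer", size = 1, signed = FALSE),
  MET_CHAR   = list(what = "integer", size = 1, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2, signed = FALSE),
  MET_SHORT  = list(what = "integer", size = 2, signed = TRUE),
  MET_UINT   = list(what = "integer", size = 4, signed = FALSE),
  MET_INT    = list(what = "integer", size = 4, signed = TRUE),
  MET_FLOAT  = list(what = "double", size = 4, signed = TRUE),
  MET_DOUBLE = list(what = "double", size = 8, signed = TRUE))

# Rescale intensities to the working 0-255 scale; the applied factor is kept
# on the volume so the original values remain recoverable.
.rescale_255 <- function(data) {
  mx <- max(data)
  if (mx <= 255 || mx == 0) return(list(data = data, factor = 1))
  f <- 255 / mx
  list(data = data * f, factor = f)
}

#' Read a 3D volume from disk
#'
#' Supports MetaImage (`.mha`, uncompressed local data), NIfTI
#' (`.nii`/`.nii.gz`) and TIFF slice stacks (a directory of single-slice
#' TIFFs, or one multi-page TIFF, with a YAML spacing sidecar). Intensities
#' wider than the 0-255 working scale are rescaled linearly by `255 / max`
#' and the factor recorded in the volume's `scaleFactor`.
#'
#' @param path file (or, for TIFF stacks, directory) to read.
#' @return A [ScanVolume-class].
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (dir.exists(path)) return(.read_tiff_stack(path))
  low <- tolower(path)
  if (grepl("\\.mha$", low)) return(.read_mha(path))
  if (grepl("\\.nii(\\.gz)?$", low)) return(.read_nifti(path))
  if (grepl("\\.tiff?$", low)) return(.read_tiff_stack(path))
  stop("unsupported volume format: ", path)
}

#' Write a 3D volume
#'
#' MetaImage is written as MET_DOUBLE with local binary data; NIfTI via
#' RNifti with the grid affine in the sform.
#'
#' @param vol a [ScanVolume-class].
#' @param path output path ending in `.mha`, `.nii` or `.nii.gz`.
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "ScanVolume"))
  low <- tolower(path)
  if (grepl("\\.mha$", low)) return(.write_mha(vol, path))
  if (grepl("\\.nii(\\.gz)?$", low)) return(.write_nifti(vol, path))
  stop("unsupported output format: ", path)
}

.read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line)) stop("malformed MetaImage header (no ElementDataFile)")
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3) stop("malformed MetaImage header line: ", line)
    hdr[[kv[2]]] <- trimws(kv[3])
    if (kv[2] == "ElementDataFile") break
  }
  if (!is.null(hdr$CompressedData) && toupper(hdr$CompressedData) == "TRUE")
    stop("compressed MetaImage data is not supported")
  if (is.null(hdr$NDims) || as.integer(hdr$NDims) != 3L)
    stop("non-3D payload: NDims = ", hdr$NDims %||% "absent")
  if (is.null(hdr$DimSize)) stop("missing MetaImage field: DimSize")
  if (is.null(hdr$ElementSpacing))
    stop("missing MetaImage field: ElementSpacing")
  d <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  sp <- as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]])
  org <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  axes <- if (!is.null(hdr$TransformMatrix))
    matrix(as.numeric(strsplit(hdr$TransformMatrix, "\\s+")[[1]]), 3, 3)
  else diag(3)
  type <- hdr$ElementType %||% "MET_UCHAR"
  tinfo <- .MHA_TYPES[[type]]
  if (is.null(tinfo)) stop("unsupported ElementType: ", type)
  if (hdr$ElementDataFile != "LOCAL")
    stop("only ElementDataFile = LOCAL is supported")
  msb <- !is.null(hdr$BinaryDataByteOrderMSB) &&
    toupper(hdr$BinaryDataByteOrderMSB) == "TRUE"
  n <- prod(d)
  raw <- readBin(con, what = tinfo$what, n = n, size = tinfo$size,
                 signed = if (tinfo$size <= 2) tinfo$signed else TRUE,
                 endian = if (msb) "big" else "little")
  if (length(raw) != n) stop("truncated MetaImage data")
  data <- array(as.double(raw), dim = d)
  wide <- !(type %in% c("MET_UCHAR", "MET_CHAR"))
  rs <- if (wide) .rescale_255(data) else list(data = data, factor = 1)
  ScanVolume(rs$data, spacing = sp, origin = org, axes = axes,
             scaleFactor = rs$factor)
}

.write_mha <- function(vol, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  d <- dim(vol@data)
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False", "CompressedData = False",
           sprintf("TransformMatrix = %s",
                   paste(format(vol@axes, digits = 17, trim = TRUE),
                         collapse = " ")),
           sprintf("Offset = %s",
                   paste(format(vol@origin, digits = 17, trim = TRUE),
                         collapse = " ")),
           sprintf("ElementSpacing = %s",
                   paste(format(vol@spacing, digits = 17, trim = TRUE),
                         collapse = " ")),
           sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
           "ElementType = MET_DOUBLE", "ElementDataFile = LOCAL")
  writeLines(hdr, con)
  writeBin(as.vector(vol@data), con, size = 8, endian = "little")
  invisible(path)
}

.read_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  M <- RNifti::xform(img)
  data <- array(as.double(img), dim = dim(img))
  if (length(dim(data)) != 3L) stop("non-3D payload in ", path)
  A <- M[1:3, 1:3]
  sp <- sqrt(colSums(A^2))
  if (any(sp <= 0)) stop("missing spacing metadata (degenerate xform) in ",
                         path)
  axes <- sweep(A, 2, sp, "/")
  rs <- .rescale_255(data)
  ScanVolume(rs$data, spacing = sp, origin = M[1:3, 4], axes = axes,
             scaleFactor = rs$factor)
}

.write_nifti <- function(vol, path) {
  img <- RNifti::asNifti(vol@data, pixdim = vol@spacing)
  M <- rbind(cbind(vol@axes %*% diag(vol@spacing), vol@origin), c(0, 0, 0, 1))
  RNifti::sform(img) <- structure(M, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

.read_tiff_stack <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                             ignore.case = TRUE))
    if (!length(files)) stop("no TIFF slices found in ", path)
    slices <- lapply(files, function(f)
      tiff::readTIFF(f, as.is = TRUE, all = FALSE))
    sidecar <- file.path(path, "spacing.yaml")
  } else {
    slices <- tiff::readTIFF(path, as.is = TRUE, all = TRUE)
    if (!is.list(slices)) slices <- list(slices)
    sidecar <- paste0(path, ".yaml")
  }
  if (!file.exists(sidecar))
    stop("missing spacing metadata: sidecar not found at ", sidecar)
  meta <- yaml::read_yaml(sidecar)
  if (is.null(meta$spacing))
    stop("missing spacing metadata: field 'spacing' absent in ", sidecar)
  slices <- lapply(slices, function(s) {
    if (length(dim(s)) == 3L) s <- s[, , 1] # first channel
    t(s) # rows (y) -> second index
  })
  d <- dim(slices[[1]])
  data <- array(0, c(d[1], d[2], length(slices)))
  for (k in seq_along(slices)) data[, , k] <- slices[[k]]
  rs <- .rescale_255(data)
  ScanVolume(rs$data, spacing = as.numeric(meta$spacing),
             origin = as.numeric(meta$origin %||% c(0, 0, 0)),
             axes = if (!is.null(meta$axes))
               matrix(as.numeric(unlist(meta$axes)), 3, 3) else diag(3),
             scaleFactor = rs$factor)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a direction field as legacy-VTK POLYDATA
#'
#' Writes one point per non-missing voxel at its world position (mm) with a
#' 3-component `VECTORS direction` attribute; missing voxels are omitted.
#'
#' @param field a [DirectionField-class] with at least one non-missing voxel.
#' @param path output `.vtk` path.
#' @export
writeVectorField <- function(field, path) {
  stopifnot(is(field, "DirectionField"))
  sup <- supportMask(field)
  n <- sum(sup)
  if (n == 0L) stop("empty field")
  idx <- which(sup, arr.ind = TRUE) - 1L
  pts <- voxelToWorld(field, idx)
  v <- matrix(field@vectors, ncol = 3)[which(sup), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "penna3d fascicle directions",
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", n)), con)
  utils::write.table(format(pts, digits = 9, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(c(sprintf("POINT_DATA %d", n), "VECTORS direction float"), con)
  utils::write.table(format(v, digits = 9, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read points and vectors back from a legacy-VTK POLYDATA file
#'
#' @param path `.vtk` file written by [writeVectorField()].
#' @return list with `points` (Nx3 mm) and `vectors` (Nx3).
#' @export
readVectorFieldPoints <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)
  if (!length(ip)) stop("no POINTS section in ", path)
  n <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  pts <- matrix(scan(text = lines[(ip + 1):(ip + n)], quiet = TRUE),
                ncol = 3, byrow = TRUE)
  iv <- grep("^VECTORS", lines)
  if (!length(iv)) stop("no VECTORS section in ", path)
  vec <- matrix(scan(text = lines[(iv + 1):(iv + n)], quiet = TRUE),
                ncol = 3, byrow = TRUE)
  list(points = pts, vectors = vec)
}

#' Read or write a pipeline configuration as YAML
#'
#' @param path YAML file.
#' @return [readPipelineConfig()] returns a [PipelineConfig-class].
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  fr <- y$frangi %||% list()
  pr <- y$prune %||% list()
  sm <- y$smooth %||% list()
  PipelineConfig(
    frangi = FrangiParams(sigma = fr$sigma %||% 2, beta = fr$beta %||% 0.5,
                          c = fr$c %||% 15, plane = fr$plane %||% "yz"),
    prune = PruneParams(hessianSigma = pr$hessianSigma %||% 2,
                        binarizeFraction = pr$binarizeFraction %||% 0.10,
                        shrinkVoxels = pr$shrinkVoxels %||% 10L,
                        lengthFraction = pr$lengthFraction %||% 0.50,
                        minNeighbors = pr$minNeighbors %||% 18L),
    smooth = SmoothParams(sMain = sm$sMain %||% 35,
                          sExtrap = sm$sExtrap %||% 0.5,
                          robust = sm$robust %||% FALSE,
                          maxIter = sm$maxIter %||% 100L,
                          tol = sm$tol %||% 1e-3),
    resampleN = y$resampleN %||% 5000L, seed = y$seed %||% 1L)
}

#' @rdname readPipelineConfig
#' @param config a [PipelineConfig-class].
#' @export
writePipelineConfig <- function(config, path) {
  y <- list(
    frangi = list(sigma = config@frangi@sigma, beta = config@frangi@beta,
                  c = config@frangi@c, plane = config@frangi@plane),
    prune = list(hessianSigma = config@prune@hessianSigma,
                 binarizeFraction = config@prune@binarizeFraction,
                 shrinkVoxels = config@prune@shrinkVoxels,
                 lengthFraction = config@prune@lengthFraction,
                 minNeighbors = config@prune@minNeighbors),
    smooth = list(sMain = config@smooth@sMain, sExtrap = config@smooth@sExtrap,
                  robust = config@smooth@robust,
                  maxIter = config@smooth@maxIter, tol = config@smooth@tol),
    resampleN = config@resampleN, seed = config@seed)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Export ground-truth directions of a synthetic scene as JSON
#'
#' @param truth a [GroundTruth-class].
#' @param path output `.json` path.
#' @export
writeGroundTruth <- function(truth, path) {
  jsonlite::write_json(list(directions = truth@directions,
                            trueAngle = truth@trueAngle,
                            apoDirection = truth@apoDirection),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
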