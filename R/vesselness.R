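# Slice-wise multiscale vessel enhancement (Frangi) filtering of masked
# volumes and re-stitching into a filtered 3D volume.

#' Frangi vesselness of a single 2D slice
#'
#' Single-scale evaluation at `p@sigma` (one scale per data type). Per pixel
#' the eigenvalues `|l1| <= |l2|` of the scale-normalized Hessian give
#' `V = exp(-(l1/l2)^2 / (2 beta^2)) * (1 - exp(-(l1^2 + l2^2) / (2 c^2)))`,
#' set to 0 for bright-on-dark polarity wherever `l2 >= 0` (a vanishing
#' second eigenvalue carries no ridge evidence and is treated as
#' background).
#'
#' @param image 2D numeric matrix (0-255 scale intensities).
#' @param p a [FrangiParams-class].
#' @return vesselness map in `[0, 1]`, same dimensions as `image`.
#' @export
frangiSlice <- function(image, p = FrangiParams()) {
  if (length(p@sigma) > 1L) {
    # optional multi-scale variant: pointwise maximum over the scale list
    out <- NULL
    for (s in p@sigma) {
      ps <- new("FrangiParams", sigma = s, beta = p@beta, c = p@c,
                plane = p@plane)
      v <- frangiSlice(image, ps)
      out <- if (is.null(out)) v else pmax(out, v)
    }
    return(out)
  }
  H <- hessian2D(image, p@sigma)
  tr2 <- (H$xx + H$yy) / 2
  disc <- sqrt(((H$xx - H$yy) / 2)^2 + H$xy^2)
  mu1 <- tr2 + disc
  mu2 <- tr2 - disc
  # order by magnitude: |l1| <= |l2|
  swap <- abs(mu1) > abs(mu2)
  l1 <- ifelse(swap, mu2, mu1)
  l2 <- ifelse(swap, mu1, mu2)
  rb2 <- ifelse(l2 != 0, (l1 / l2)^2, 0)
  s2 <- l1^2 + l2^2
  v <- exp(-rb2 / (2 * p@beta^2)) * (1 - exp(-s2 / (2 * p@c^2)))
  v[l2 >= 0] <- 0 # bright-on-dark polarity; l2 == 0 treated as background
  pmin(pmax(v, 0), 1)
}

#' Slice-wise vessel enhancement of a masked volume
#'
#' Sets intensities outside the compartment mask (and inside the aponeurosis
#' mask, if given) to 0, filters every sagittal slice independently with
#' [frangiSlice()] ("yz" slices for muscle volumes, "xz" for phantom
#' volumes), re-stitches the filtered slices into a volume of identical
#' geometry and rescales the result to 0-255.
#'
#' @param vol a [ScanVolume-class].
#' @param mask compartment/muscle [MaskVolume-class] (same geometry).
#' @param apoMask optional aponeurosis [MaskVolume-class]; its voxels are
#'   zeroed before filtering.
#' @param p a [FrangiParams-class].
#' @return filtered [ScanVolume-class], intensities on 0-255.
#' @export
applyMVEF <- function(vol, mask, apoMask = NULL, p = FrangiParams()) {
  stopifnot(is(vol, "ScanVolume"), is(mask, "MaskVolume"))
  .stopifnot_same_geometry(vol, mask, "volume and mask")
  if (!any(mask@data)) stop("empty mask")
  data <- vol@data
  data[!mask@data] <- 0
  if (!is.null(apoMask)) {
    .stopifnot_same_geometry(vol, apoMask, "volume and aponeurosis mask")
    data[apoMask@data] <- 0
  }
  out <- array(0, dim(data))
  if (p@plane == "xz") {
    for (j in seq_len(dim(data)[2])) {
      sl <- data[, j, ]
      if (any(sl != 0)) out[, j, ] <- frangiSlice(sl, p)
    }
  } else {
    for (i in seq_len(dim(data)[1])) {
      sl <- data[i, , ]
      if (any(sl != 0)) out[i, , ] <- frangiSlice(sl, p)
    }
  }
  out[!mask@data] <- 0
  if (!is.null(apoMask)) out[apoMask@data] <- 0
  mx <- max(out)
  if (mx > 0) out <- out * (255 / mx)
  ScanVolume(out, spacing = vol@spacing, origin = vol@origin,
             axes = vol@axes)
}
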