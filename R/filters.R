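# Gaussian (derivative) kernels and separable convolution helpers.
# Kernels are sampled from the analytic Gaussian derivatives and moment-
# normalized so the discrete operator reproduces the exact derivative of
# low-order polynomials; boundaries are reflective.

.gauss_kernel <- function(sigma, order = 0L) {
  r <- max(1L, as.integer(ceiling(5 * sigma)))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  if (order == 0L) return(g / sum(g))
  if (order == 1L) {
    # correlation kernel for d/dx: reversed first derivative of the Gaussian
    k <- x * g / sigma^2
    return(k / sum(k * x)) # exact on ramps
  }
  if (order == 2L) {
    k <- (x^2 / sigma^4 - 1 / sigma^2) * g
    k <- k - mean(k) # zero response to constants
    return(k / (sum(k * x^2) / 2)) # exact second derivative of x^2/2
  }
  stop("order must be 0, 1 or 2")
}

.as_cube <- function(a) {
  if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
  a
}

# separable convolution of a 3D array; any of kx/ky/kz may be NULL (skip)
.conv3 <- function(a, kx = NULL, ky = NULL, kz = NULL) {
  a <- .as_cube(a)
  if (!is.null(kx)) a <- cpp_conv_dim(a, kx, 1L)
  if (!is.null(ky)) a <- cpp_conv_dim(a, ky, 2L)
  if (!is.null(kz) && dim(a)[3] > 1L) a <- cpp_conv_dim(a, kz, 3L)
  a
}

# 3D Gaussian smoothing with per-axis sigma in voxels
.gauss3 <- function(a, sigma) {
  sigma <- rep(sigma, length.out = 3)
  k <- lapply(sigma, function(s) if (s > 0.05) .gauss_kernel(s, 0L) else NULL)
  .conv3(a, k[[1]], k[[2]], k[[3]])
}

# Full 3D Hessian (six unique second Gaussian derivatives) at one scale,
# gamma = 2 normalized (responses multiplied by sigma^2). Shares the
# intermediate separable passes across components.
.hessian3 <- function(a, sigma) {
  a <- .as_cube(a)
  g0 <- .gauss_kernel(sigma, 0L)
  g1 <- .gauss_kernel(sigma, 1L)
  g2 <- .gauss_kernel(sigma, 2L)
  s2 <- sigma^2
  z0 <- cpp_conv_dim(a, g0, 3L)
  z1 <- cpp_conv_dim(a, g1, 3L)
  z2 <- cpp_conv_dim(a, g2, 3L)
  y00 <- cpp_conv_dim(z0, g0, 2L)
  y01 <- cpp_conv_dim(z0, g1, 2L)
  y02 <- cpp_conv_dim(z0, g2, 2L)
  y10 <- cpp_conv_dim(z1, g0, 2L)
  y11 <- cpp_conv_dim(z1, g1, 2L)
  y20 <- cpp_conv_dim(z2, g0, 2L)
  list(xx = s2 * cpp_conv_dim(y00, g2, 1L),
       xy = s2 * cpp_conv_dim(y01, g1, 1L),
       xz = s2 * cpp_conv_dim(y10, g1, 1L),
       yy = s2 * cpp_conv_dim(y02, g0, 1L),
       yz = s2 * cpp_conv_dim(y11, g0, 1L),
       zz = s2 * cpp_conv_dim(y20, g0, 1L))
}

#' Scale-normalized 2D Hessian by Gaussian derivatives
#'
#' Second-order Gaussian-derivative responses at a single scale, multiplied
#' by `sigma^2` (gamma = 2 scale normalization), with reflective boundary
#' handling.
#'
#' @param image 2D numeric matrix, at least 5 x 5, finite.
#' @param sigma Gaussian scale in pixels.
#' @return list with `xx`, `xy`, `yy` response matrices.
#' @export
hessian2D <- function(image, sigma) {
  if (!is.matrix(image) || any(dim(image) < 5L))
    stop("image must be a matrix of at least 5 x 5 pixels")
  if (any(!is.finite(image))) stop("image contains non-finite pixels")
  if (sigma <= 0) stop("sigma must be > 0")
  a <- .as_cube(image)
  g0 <- .gauss_kernel(sigma, 0L)
  g1 <- .gauss_kernel(sigma, 1L)
  g2 <- .gauss_kernel(sigma, 2L)
  s2 <- sigma^2
  list(xx = s2 * cpp_conv_dim(cpp_conv_dim(a, g2, 1L), g0, 2L)[, , 1],
       xy = s2 * cpp_conv_dim(cpp_conv_dim(a, g1, 1L), g1, 2L)[, , 1],
       yy = s2 * cpp_conv_dim(cpp_conv_dim(a, g0, 1L), g2, 2L)[, , 1])
}
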