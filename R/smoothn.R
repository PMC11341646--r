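# Penalized least-squares smoothing of gridded data with missing values,
# solved spectrally in the DCT domain: minimize
#   ||W^(1/2) (z - y)||^2 + s ||L z||^2
# with L the 3D discrete Laplacian under reflective (Neumann) boundaries,
# whose eigenbasis is the DCT-II. Missing voxels get weight 0 and are
# recovered by fixed-point iteration; the fixed point solves the weighted
# normal equations (W + s L'L) z = W y exactly.

.dct_cache <- new.env(parent = emptyenv())

# orthonormal DCT-II matrix: forward y = C x, inverse x = t(C) y
.dct_mat <- function(n) {
  key <- as.character(n)
  C <- .dct_cache[[key]]
  if (is.null(C)) {
    k <- 0:(n - 1)
    j <- 0:(n - 1)
    C <- sqrt(2 / n) * cos(pi * outer(k, 2 * j + 1) / (2 * n))
    C[1, ] <- sqrt(1 / n)
    .dct_cache[[key]] <- C
  }
  C
}

# apply the (inverse) DCT along every dimension of a 3D array
.dct3 <- function(a, inverse = FALSE) {
  for (d in 1:3) {
    dm <- dim(a)
    C <- .dct_mat(dm[1])
    if (inverse) C <- t(C)
    a <- aperm(array(C %*% matrix(a, nrow = dm[1]), dm), c(2, 3, 1))
  }
  a
}

# eigenvalues of the Neumann Laplacian on the grid, as a 3D array
.laplacian_eigenvalues <- function(d) {
  lam <- lapply(d, function(n) -2 + 2 * cos(pi * (0:(n - 1)) / n))
  outer(outer(lam[[1]], lam[[2]], "+"), lam[[3]], "+")
}

# Smooth one scalar component. y: 3D array with NaN/NA at missing voxels;
# w: non-negative weights (0 = missing). Returns the full in/extrapolated
# grid.
.smooth_component <- function(y, w, s, maxIter = 100L, tol = 1e-3,
                              robust = FALSE) {
  d <- dim(y)
  if (all(w <= 0)) stop("all-missing component")
  obs <- w > 0
  if (s == 0 && all(obs)) return(y)
  Gamma <- 1 / (1 + s * .laplacian_eigenvalues(d)^2)
  yfill <- y
  yfill[!obs] <- mean(y[obs])
  z <- yfill
  W <- w
  n_robust <- if (robust) 3L else 1L
  for (r in seq_len(n_robust)) {
    if (all(obs) && !robust) {
      # no missing voxels: the spectral solve is exact in one step
      z <- .dct3(Gamma * .dct3(yfill), inverse = TRUE)
      break
    }
    RF <- 1.75 # over-relaxation speeds the fixed-point iteration
    for (it in seq_len(maxIter)) {
      A <- z
      A[obs] <- W[obs] * (y[obs] - z[obs]) + z[obs]
      zhat <- .dct3(Gamma * .dct3(A), inverse = TRUE)
      dz <- sqrt(sum((zhat - z)^2)) / max(sqrt(sum(zhat^2)), .Machine$double.eps)
      z <- RF * zhat + (1 - RF) * z
      if (dz < tol) break
    }
    if (robust && r < n_robust) {
      res <- (y - z)[obs]
      sig <- 1.4826 * stats::median(abs(res - stats::median(res)))
      if (sig <= .Machine$double.eps) break
      u <- res / (4.685 * sig)
      W[obs] <- w[obs] * ifelse(abs(u) < 1, (1 - u^2)^2, 0)
      if (all(W[obs] == 0)) stop("robust weighting removed all observations")
    }
  }
  z
}

#' Penalized least-squares smoothing of a direction field
#'
#' Smooths each vector component on its grid by minimizing
#' `||W^1/2 (z - y)||^2 + s ||Lz||^2` (L = discrete Laplacian, reflective
#' boundaries), solved spectrally via the DCT. Missing voxels (weight 0) are
#' in/extrapolated, so the returned field is defined on the whole grid.
#' Components are smoothed independently; re-normalize downstream if unit
#' vectors are required.
#'
#' @param field a [DirectionField-class] with at least one non-missing voxel.
#' @param s smoothing parameter (>= 0); `s = 0` with no missing voxels
#'   returns the input.
#' @param robust enable bisquare reweighting of residuals.
#' @param maxIter,tol fixed-point iteration controls for missing values.
#' @return A [DirectionField-class] defined on the full grid.
#' @export
smoothField <- function(field, s = 35, robust = FALSE, maxIter = 100L,
                        tol = 1e-3) {
  stopifnot(is(field, "DirectionField"))
  if (s < 0) stop("s must be >= 0")
  sup <- supportMask(field)
  if (!any(sup)) stop("all-missing component")
  w <- array(as.numeric(sup), dim(sup))
  v <- field@vectors
  out <- array(NaN, dim(v))
  for (comp in 1:3)
    out[, , , comp] <- .smooth_component(v[, , , comp], w, s,
                                         maxIter = maxIter, tol = tol,
                                         robust = robust)
  DirectionField(out, spacing = field@spacing, origin = field@origin,
                 axes = field@axes)
}

# scalar-array interface used by tests and fillMuscle
.smooth_array <- function(y, s, maxIter = 100L, tol = 1e-3, robust = FALSE,
                          w = NULL) {
  if (is.null(w)) w <- array(as.numeric(is.finite(y)), dim(y))
  .smooth_component(y, w, s, maxIter = maxIter, tol = tol, robust = robust)
}
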