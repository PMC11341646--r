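# Analytic test scenes built in code.

# bright Gaussian-profile tube through `centre` (1-based voxel coords) along
# unit direction `u` (index space), amplitude 200, radial sigma in voxels
tube_volume <- function(d, u, centre = (d + 1) / 2, radius = 2,
                        amplitude = 200, spacing = c(1, 1, 1)) {
  idx <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
  rel <- sweep(idx, 2, centre)
  t1 <- rel %*% u
  perp2 <- pmax(rowSums(rel^2) - as.vector(t1)^2, 0)
  ScanVolume(array(amplitude * exp(-perp2 / (2 * radius^2)), d),
             spacing = spacing)
}

# solid cuboid mask given inclusive 1-based index ranges
cuboid_mask <- function(d, xr, yr, zr, spacing = c(1, 1, 1)) {
  a <- array(FALSE, d)
  a[xr[1]:xr[2], yr[1]:yr[2], zr[1]:zr[2]] <- TRUE
  MaskVolume(a, spacing = spacing)
}

# direction field with every voxel set to `v` inside `mask` (logical array)
uniform_field <- function(d, v, mask = array(TRUE, d), spacing = c(1, 1, 1)) {
  vec <- array(NaN, c(d, 3))
  for (i in 1:3) {
    comp <- array(NaN, d)
    comp[mask] <- v[i]
    vec[, , , i] <- comp
  }
  DirectionField(vec, spacing = spacing)
}

# dense direct solve of the penalized least-squares system
# (W + s L'L) z = W y with the Neumann-Laplacian L, as an independent oracle
dense_smooth_oracle <- function(y, s) {
  d <- dim(y)
  lap1 <- function(n) {
    L <- diag(-2, n)
    if (n > 1) {
      L[cbind(1:(n - 1), 2:n)] <- 1
      L[cbind(2:n, 1:(n - 1))] <- 1
      L[1, 1] <- -1
      L[n, n] <- -1
    }
    L
  }
  I1 <- Matrix::Diagonal(d[1]); I2 <- Matrix::Diagonal(d[2])
  I3 <- Matrix::Diagonal(d[3])
  L <- Matrix::kronecker(I3, Matrix::kronecker(I2, Matrix::Matrix(lap1(d[1])))) +
    Matrix::kronecker(I3, Matrix::kronecker(Matrix::Matrix(lap1(d[2])), I1)) +
    Matrix::kronecker(Matrix::Matrix(lap1(d[3])), Matrix::kronecker(I2, I1))
  w <- as.numeric(is.finite(y))
  yv <- ifelse(is.finite(y), y, 0)
  z <- Matrix::solve(Matrix::Diagonal(x = w) + s * Matrix::crossprod(L),
                     w * yv)
  array(as.numeric(z), d)
}

angle_deg <- function(a, b) {
  acos(min(max(abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2)), 0), 1)) * 180 / pi
}
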