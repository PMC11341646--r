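test_that("2D Hessian matches the analytic Gaussian derivative", {
  si <- 4; sf <- 2
  n <- 41; ctr <- 21
  x <- outer(0:(n - 1) - ctr + 1, rep(1, n)); y <- t(x)
  img <- exp(-(x^2 + y^2) / (2 * si^2))
  H <- hessian2D(img, sf)
  st2 <- si^2 + sf^2
  expected <- -sf^2 * (si^2 / st2) / st2 # gamma-normalized d2/dx2 at centre
  expect_equal(H$xx[ctr, ctr], expected, tolerance = 1e-3)
  expect_equal(H$yy[ctr, ctr], expected, tolerance = 1e-3)
  # symmetry under transpose: Hxy(img') = Hxy(img)'
  Ht <- hessian2D(t(img), sf)
  expect_equal(Ht$xy, t(H$xy), tolerance = 1e-12)
  expect_equal(Ht$xx, t(H$yy), tolerance = 1e-12)
})

test_that("2D Hessian of a constant image is zero and bad input errors", {
  H <- hessian2D(matrix(7, 20, 20), 2)
  expect_lt(max(abs(c(H$xx, H$xy, H$yy))), 1e-12)
  expect_error(hessian2D(matrix(c(NA, runif(99)), 10, 10), 2), "finite")
  expect_error(hessian2D(matrix(0, 3, 3), 2), "5 x 5")
})

test_that("Frangi vesselness: polarity, ridge response and invariances", {
  p <- FrangiParams(sigma = 2)
  expect_equal(max(frangiSlice(matrix(50, 30, 30), p)), 0)
  img <- matrix(0, 40, 40)
  img[, 19:21] <- 200 # bright ridge of width ~ sigma
  v <- frangiSlice(img, p)
  expect_gt(v[20, 20], v[20, 20 - 6]) # centreline beats 3*sigma off-line
  expect_true(all(v >= 0 & v <= 1))
  # dark ridge on bright ground gives zero at the centreline
  vd <- frangiSlice(200 - img, p)
  expect_equal(vd[20, 20], 0)
  # invariant to adding a constant
  expect_equal(frangiSlice(img + 30, p), v, tolerance = 1e-12)
  # equivariant under 90-degree rotation
  rot90 <- function(m) t(m)[ncol(m):1, ]
  expect_equal(frangiSlice(rot90(img), p), rot90(v), tolerance = 1e-12)
})

test_that("finite-difference Hessian oracle agrees on a ridge profile", {
  # independent oracle: central finite differences of the Gaussian-blurred
  # image reproduce the operator's eigen-structure on a smooth ridge
  n <- 41
  x <- outer(seq_len(n) - 21, rep(1, n))
  img <- 200 * exp(-x^2 / (2 * 9)) # vertical ridge, sigma_r = 3
  sf <- 2
  H <- hessian2D(img, sf)
  g <- penna3d:::.gauss_kernel(sf, 0L)
  sm <- penna3d:::cpp_conv_dim(
    penna3d:::cpp_conv_dim(array(img, c(n, n, 1)), g, 1L), g, 2L)[, , 1]
  fd_xx <- sf^2 * (sm[20, 21] - 2 * sm[21, 21] + sm[22, 21])
  expect_equal(H$xx[21, 21], fd_xx, tolerance = 0.02 * abs(fd_xx))
  # ridge direction: |lambda| smallest along the ridge => Hyy ~ 0, Hxx < 0
  expect_lt(H$xx[21, 21], 0)
  expect_lt(abs(H$yy[21, 21]), abs(H$xx[21, 21]) / 20)
})

test_that("applyMVEF masks, zeroes the aponeurosis, and rescales to 0-255", {
  d <- c(24, 30, 20)
  vol <- tube_volume(d, c(0, 0, 1), centre = c(12, 15, 10), radius = 2)
  mask <- cuboid_mask(d, c(3, 22), c(3, 28), c(1, 20))
  apo <- cuboid_mask(d, c(3, 22), c(26, 28), c(1, 20))
  out <- applyMVEF(vol, mask, apo, FrangiParams(sigma = 2, plane = "yz"))
  expect_equal(dims(out), d)
  expect_true(all(out@data[!mask@data] == 0))
  expect_true(all(out@data[apo@data] == 0))
  expect_equal(max(out@data), 255)
  # all-zero masked volume -> all-zero output
  z <- ScanVolume(array(0, d))
  expect_equal(max(applyMVEF(z, mask, NULL, FrangiParams())@data), 0)
  expect_error(applyMVEF(vol, MaskVolume(array(FALSE, d)), NULL,
                         FrangiParams()), "empty mask")
})

test_that("wire-phantom slice puts wire pixels in the top decile of MVEF output", {
  ph <- generateWirePhantom(WirePhantomSpec(seed = 3L))
  vol <- ph$volume
  mask <- ph$truth@masks$A
  out <- applyMVEF(vol, mask, NULL, FrangiParams(sigma = 3.5, plane = "xz"))
  # wire voxels: brightest 1% of the clean volume inside the mask
  cl <- ph$clean@data
  wire <- cl >= 0.5 * max(cl) & mask@data
  thr <- stats::quantile(out@data[mask@data], 0.9)
  expect_gt(mean(out@data[wire] >= thr), 0.6)
})
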