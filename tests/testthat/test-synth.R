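test_that("wire phantom ground-truth angle matches the spec exactly", {
  ph <- generateWirePhantom(WirePhantomSpec(seed = 1L))
  tr <- ph$truth
  ang <- angle_deg(tr@directions$A, tr@directions$B)
  expect_equal(ang, 10.78, tolerance = 1e-9)
  expect_equal(sqrt(sum(tr@directions$A^2)), 1, tolerance = 1e-12)
})

test_that("noise-free wires trace bright lines along the group direction", {
  spec <- WirePhantomSpec(rowsA = 1L, colsA = 1L, nB = 1L,
                          interGroupAngle = 0.5, wallSeparation = 10,
                          noise = SpeckleParams(psfSigma = c(0, 0),
                                                multSigma = 0, addSigma = 0))
  ph <- generateWirePhantom(spec)
  a <- ph$clean@data
  # centreline voxels are far brighter than water (anti-aliased splatting
  # dims sub-voxel-offset segments, so the peak need not reach 255)
  expect_gt(max(a), 100)
  mx_per_slice <- apply(a, 3, max)
  expect_true(all(mx_per_slice > spec@intensities[["water"]]))
  # bright voxels concentrate near constant (x, y) per z for near-axial wires
  pos <- t(vapply(seq_len(dim(a)[3]), function(k) {
    i <- which(a[, , k] == max(a[, , k]), arr.ind = TRUE)[1, ]
    as.numeric(i)
  }, numeric(2)))
  expect_lt(diff(range(pos[, 2])), 3) # y stays put
})

test_that("two phantom seeds differ voxelwise but share ground truth", {
  p1 <- generateWirePhantom(WirePhantomSpec(seed = 1L))
  p2 <- generateWirePhantom(WirePhantomSpec(seed = 2L))
  expect_false(identical(p1$volume@data, p2$volume@data))
  expect_identical(p1$truth@directions, p2$truth@directions)
  expect_identical(p1$truth@masks$A@data, p2$truth@masks$A@data)
})

test_that("phantom compartment masks are non-empty and disjoint", {
  ph <- generateWirePhantom(WirePhantomSpec(seed = 1L))
  a <- ph$truth@masks$A@data
  b <- ph$truth@masks$B@data
  expect_gt(sum(a), 0)
  expect_gt(sum(b), 0)
  expect_equal(sum(a & b), 0)
})

test_that("pennate muscle ground truth is bimodal at the programmed angles", {
  mu <- generatePennateMuscle(PennateMuscleSpec(seed = 1L))
  tr <- mu$truth
  am <- tr@angleMap
  sup <- tr@masks$superficial@data
  deep <- tr@masks$deep@data
  expect_true(all(am[sup] == 5))
  expect_true(all(am[deep] == 10))
  expect_gt(sum(sup), 0)
  expect_gt(sum(deep), 0)
  expect_equal(sum(sup & deep), 0)
  # programmed directions at the programmed pennation to the aponeurosis
  expect_equal(angle_deg(tr@directions$superficial, tr@apoDirection), 5,
               tolerance = 1e-9)
  expect_equal(angle_deg(tr@directions$deep, tr@apoDirection), 10,
               tolerance = 1e-9)
})

test_that("zero pennation aligns all true directions with the aponeurosis", {
  mu <- generatePennateMuscle(PennateMuscleSpec(pennationSuperficial = 0,
                                                pennationDeep = 0))
  expect_equal(mu$truth@directions$superficial, c(0, 0, 1))
  expect_equal(mu$truth@directions$deep, c(0, 0, 1))
})

test_that("speckle model: identity at zero sigmas, deterministic, unbiased", {
  v <- ScanVolume(array(100, c(12, 12, 12)))
  p0 <- SpeckleParams(psfSigma = c(0, 0), multSigma = 0, addSigma = 0)
  expect_equal(addSpeckle(v, p0, seed = 1L)@data, v@data)
  p <- SpeckleParams(psfSigma = c(0, 0), multSigma = 0.1, addSigma = 0)
  n1 <- addSpeckle(v, p, seed = 5L)
  n2 <- addSpeckle(v, p, seed = 5L)
  expect_identical(n1@data, n2@data)
  expect_false(identical(n1@data, addSpeckle(v, p, seed = 6L)@data))
  # law of large numbers: multiplicative noise leaves the mean within 1%
  expect_lt(abs(mean(n1@data) - 100) / 100, 0.01)
})

test_that("incompatible pennate geometry errors", {
  expect_error(generatePennateMuscle(
    PennateMuscleSpec(apoThickness = 20, semiAxes = c(7, 7, 19))),
    "incompatible")
})
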