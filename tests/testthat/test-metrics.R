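test_that("aponeurosis direction: straight segment, tilted plate, sign", {
  d <- c(20, 20, 20)
  seg <- array(FALSE, d); seg[10, 3:18, 10] <- TRUE
  expect_equal(aponeurosisDirection(MaskVolume(seg), longAxis = c(0, 1, 0)),
               c(0, 1, 0), tolerance = 1e-9)
  # thin tilted plate: in-plane long axis matches the covariance eigen oracle
  idx <- as.matrix(expand.grid(1:30, 1:30, 1:30))
  th <- 20 * pi / 180
  n <- c(0, cos(th), -sin(th)) # plate normal in yz
  ctr <- c(15, 15, 15)
  rel <- sweep(idx, 2, ctr)
  plate <- abs(rel %*% n) < 1 & abs(rel[, 1]) < 4 & rowSums(rel^2) < 170
  mk <- MaskVolume(array(plate, c(30, 30, 30)))
  e1 <- eigen(stats::cov(idx[plate, ] - 1), symmetric = TRUE)$vectors[, 1]
  got <- aponeurosisDirection(mk)
  expect_lt(angle_deg(got, e1), 1e-4)
  expect_gte(got[3], 0) # sign convention: non-negative long-axis component
  expect_error(aponeurosisDirection(MaskVolume(array(FALSE, d))), "mask")
})

test_that("pennation angles fold to [0, 90] and keep missing voxels missing", {
  d <- c(3, 3, 3)
  a <- c(0, 0, 1)
  vec <- array(NaN, c(d, 3))
  vec[1, 1, 1, ] <- c(0, 0, 1)                                  # parallel
  vec[2, 1, 1, ] <- c(1, 0, 0)                                  # perpendicular
  vec[3, 1, 1, ] <- c(0, sin(170 * pi / 180), cos(170 * pi / 180)) # 170 deg
  f <- DirectionField(vec)
  ang <- pennationAngles(f, a)
  expect_equal(ang[1, 1, 1], 0, tolerance = 1e-9)
  expect_equal(ang[2, 1, 1], 90, tolerance = 1e-9)
  expect_equal(ang[3, 1, 1], 10, tolerance = 1e-9)
  expect_true(is.nan(ang[1, 2, 1]))
  expect_error(pennationAngles(f, c(0, 0, 0)), "zero-length")
})

test_that("pennation is invariant to simultaneous rotation of field and axis", {
  set.seed(2)
  d <- c(4, 4, 4)
  v <- matrix(rnorm(prod(d) * 3), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  f <- DirectionField(array(v, c(d, 3)))
  a <- c(0, 0.6, 0.8)
  th <- 40 * pi / 180
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  fR <- DirectionField(array(v %*% t(R), c(d, 3)))
  expect_equal(pennationAngles(fR, as.numeric(R %*% a)),
               pennationAngles(f, a), tolerance = 1e-9)
})

test_that("compartment summaries are deterministic and statistically sound", {
  d <- c(20, 20, 20)
  ang <- array(7, d)
  mk <- MaskVolume(array(TRUE, d))
  s1 <- compartmentSummary(ang, mk, n = 500, seed = 4)
  expect_equal(s1$mean, 7)
  expect_equal(s1$sd, 0)
  expect_false(s1$withReplacement)
  expect_identical(s1, compartmentSummary(ang, mk, n = 500, seed = 4))
  # resampled mean within 3 SE of the population mean
  set.seed(9)
  ang2 <- array(10 + rnorm(prod(d), 0, 2), d)
  s2 <- compartmentSummary(ang2, mk, n = 1000, seed = 5)
  se <- s2$sd / sqrt(1000)
  expect_lt(abs(s2$mean - mean(ang2)), 3 * se)
  # with-replacement flag when support < n
  small <- array(FALSE, d); small[1:3, 1, 1] <- TRUE
  s3 <- compartmentSummary(ang, MaskVolume(small), n = 10, seed = 1)
  expect_true(s3$withReplacement)
  expect_error(compartmentSummary(ang * NaN, mk), "empty support")
})

test_that("phantom angle statistics behave on constructed fields", {
  d <- c(6, 6, 6)
  fA <- uniform_field(d, c(0, 0, 1))
  t1 <- 10.78
  u <- c(0, sin(t1 * pi / 180), cos(t1 * pi / 180))
  fB <- uniform_field(d, u)
  st <- phantomAngles(fA, fB, truth = t1)
  expect_equal(st@mae, 0, tolerance = 1e-9)
  expect_equal(st@meanDirectionAngle, t1, tolerance = 1e-9)
  expect_equal(st@nPairs, prod(d)^2)
  expect_false(st@subsampled)
  # identical fields: all pairwise angles 0 => MAE equals the truth
  st0 <- phantomAngles(fA, fA, truth = t1)
  expect_equal(st0@mae, t1, tolerance = 1e-9)
  # antipodal vectors in one field: mean direction is +-v, never 0
  vecs <- array(NaN, c(d, 3))
  vecs[1, 1, 1, ] <- c(0, 0, 1)
  vecs[2, 1, 1, ] <- c(0, 0, -1)
  fmix <- DirectionField(vecs)
  stm <- phantomAngles(fmix, fA, truth = 0)
  expect_equal(stm@meanDirectionAngle, 0, tolerance = 1e-9)
  expect_error(phantomAngles(DirectionField(array(NaN, c(2, 2, 2, 3))), fA, 1),
               "empty field")
})

test_that("pairwise subsampling is seeded and capped", {
  d <- c(8, 8, 8)
  fA <- uniform_field(d, c(0, 0, 1))
  fB <- uniform_field(d, c(0, 1, 0))
  st <- phantomAngles(fA, fB, truth = 90, maxPairs = 1000)
  expect_true(st@subsampled)
  expect_equal(st@nPairs, 1000)
  expect_equal(st@mae, 0, tolerance = 1e-9)
})

test_that("muscle volume is exact on analytic cuboids and rotation-stable", {
  mk <- cuboid_mask(c(10, 10, 10), c(1, 10), c(1, 10), c(1, 10))
  expect_equal(muscleVolume(mk), 1) # 1000 voxels at 1 mm^3
  mk2 <- cuboid_mask(c(12, 12, 14), c(2, 11), c(2, 11), c(3, 12),
                     spacing = c(0.17, 0.17, 0.66))
  expect_equal(muscleVolume(mk2), 1000 * 0.17 * 0.17 * 0.66 / 1000,
               tolerance = 1e-12)
  expect_equal(muscleVolume(MaskVolume(array(FALSE, c(4, 4, 4)))), 0)
  # rigid rotation changes the count by < 1%
  n <- 30
  mk3 <- cuboid_mask(c(n, n, n), c(8, 22), c(8, 22), c(5, 25))
  th <- 25 * pi / 180
  Rot <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  e1 <- Rot[, 3]; e2 <- Rot[, 2]
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2], e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  fr <- new("MuscleFrame", rotation = cbind(e1, e2, e3), centroid = c(0, 0, 0))
  expect_lt(abs(muscleVolume(rotateVolume(mk3, fr)) - muscleVolume(mk3)) /
              muscleVolume(mk3), 0.01)
})
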