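test_that("muscle frame recovers axis-aligned and rotated cuboids", {
  d <- c(30, 30, 40)
  mk <- cuboid_mask(d, c(12, 18), c(8, 22), c(5, 36))
  fr <- muscleFrame(mk)
  expect_equal(unname(abs(fr@rotation)), diag(3)[, c(3, 2, 1)], tolerance = 1e-9)
  expect_equal(unname(fr@rotation[, 1]), c(0, 0, 1)) # long axis toward +z
  expect_equal(det(fr@rotation), 1, tolerance = 1e-9)
  # rotated cuboid: recovered axes match the covariance eigen oracle
  th <- 25 * pi / 180
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  idx <- as.matrix(expand.grid(1:40, 1:40, 1:40))
  ctr <- c(20, 20, 20)
  rel <- sweep(idx, 2, ctr) %*% R # rotate sampling coords
  inb <- abs(rel[, 1]) < 4 & abs(rel[, 2]) < 8 & abs(rel[, 3]) < 16
  mk2 <- MaskVolume(array(inb, c(40, 40, 40)))
  fr2 <- muscleFrame(mk2)
  ev <- eigen(stats::cov(idx[inb, ] - 1), symmetric = TRUE)$vectors
  for (k in 1:3)
    expect_lt(angle_deg(fr2@rotation[, k], ev[, k]), 1e-4)
  # physical check: long axis within 1 degree of the rotated z axis
  expect_lt(angle_deg(fr2@rotation[, 1], R[, 3]), 1)
})

test_that("spherical masks are rejected unless explicitly allowed", {
  idx <- as.matrix(expand.grid(1:21, 1:21, 1:21))
  ball <- array(rowSums(sweep(idx, 2, c(11, 11, 11))^2) <= 64, c(21, 21, 21))
  mk <- MaskVolume(ball)
  expect_error(muscleFrame(mk), "degenerate")
  expect_s4_class(muscleFrame(mk, allowDegenerate = TRUE), "MuscleFrame")
})

test_that("rotateVolume: identity frame is exact, round trip is accurate", {
  a <- array(runif(12 * 13 * 14) * 255, c(12, 13, 14))
  v <- ScanVolume(a, spacing = c(0.5, 0.5, 1))
  fid <- new("MuscleFrame", rotation = cbind(c(0, 0, 1), c(0, 1, 0),
                                             c(-1, 0, 0)),
             centroid = c(0, 0, 0))
  expect_equal(rotateVolume(v, fid)@data, a)
  # rotate / inverse-rotate on smooth content: < 2 gray levels mean error
  th <- 25 * pi / 180
  Rot <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  e1 <- Rot[, 3]; e2 <- Rot[, 2]
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2], e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  f1 <- new("MuscleFrame", rotation = cbind(e1, e2, e3), centroid = c(0, 0, 0))
  n <- 24
  fun <- function(w) 120 + 80 * sin(w[, 1] / 5) * cos(w[, 2] / 6) * sin(w[, 3] / 7)
  idx <- as.matrix(expand.grid(1:n, 1:n, 1:n)) - 1
  vs <- ScanVolume(array(fun(idx), c(n, n, n)))
  v2 <- rotateVolume(rotateVolume(vs, f1), fid)
  d2 <- dims(v2)
  idx2 <- as.matrix(expand.grid(0:(d2[1] - 1), 0:(d2[2] - 1), 0:(d2[3] - 1)))
  w2 <- voxelToWorld(v2, idx2)
  inside <- rowSums(w2 > 5 & w2 < n - 6) == 3
  expect_lt(mean(abs(v2@data[idx2[inside, ] + 1] - fun(w2[inside, , drop = FALSE]))), 2)
  # mask voxel count conserved within 1% under rotation
  mk <- cuboid_mask(c(n, n, n), c(7, 17), c(7, 17), c(5, 19))
  mr <- rotateVolume(mk, f1)
  expect_lt(abs(sum(mr@data) - sum(mk@data)) / sum(mk@data), 0.01)
})

test_that("direction field recovers cylinder axes within 1 degree", {
  d <- c(31, 31, 41)
  vol <- tube_volume(d, c(0, 0, 1))
  df <- directionField(vol, hessianSigma = 2)
  expect_lt(angle_deg(df$field@vectors[16, 16, 21, ], c(0, 0, 1)), 1)
  th <- 30 * pi / 180
  u <- c(0, sin(th), cos(th))
  d2 <- c(25, 61, 61)
  vol2 <- tube_volume(d2, u)
  df2 <- directionField(vol2, hessianSigma = 2)
  expect_lt(angle_deg(df2$field@vectors[13, 31, 31, ], u), 1)
  # isotropic blob centre is flagged degenerate
  blob <- tube_volume(c(21, 21, 21), c(0, 0, 1), radius = 3)
  iso <- ScanVolume(array(200 * exp(-rowSums(sweep(as.matrix(
    expand.grid(1:21, 1:21, 1:21)), 2, c(11, 11, 11))^2) / 18), c(21, 21, 21)))
  dfb <- directionField(iso, hessianSigma = 2)
  expect_true(dfb$degenerate[11, 11, 11])
})

test_that("binarization threshold is 10% of max with an inclusive tie", {
  d <- c(8, 8, 8)
  a <- array(0, d)
  a[2, 2, 2] <- 200
  a[3, 3, 3] <- 20    # exactly at the cutoff: kept
  a[4, 4, 4] <- 19.99 # just below: dropped
  vol <- ScanVolume(a)
  mk <- fascicleMask(vol, MaskVolume(array(TRUE, d)),
                     PruneParams(shrinkVoxels = 0L))
  expect_true(mk@data[2, 2, 2])
  expect_true(mk@data[3, 3, 3])
  expect_false(mk@data[4, 4, 4])
  expect_error(fascicleMask(ScanVolume(array(0, d)),
                            MaskVolume(array(TRUE, d))), "all-zero")
})

test_that("mask shrinking erodes with the 6-connected element", {
  d <- c(12, 12, 12)
  comp <- cuboid_mask(d, c(2, 11), c(2, 11), c(2, 11))
  a <- array(100, d)
  mk0 <- fascicleMask(ScanVolume(a), comp, PruneParams(shrinkVoxels = 0L))
  expect_equal(sum(mk0@data), sum(comp@data)) # shrink 0: unchanged
  mk2 <- fascicleMask(ScanVolume(a), comp, PruneParams(shrinkVoxels = 2L))
  expect_equal(sum(mk2@data), 6^3) # 10^3 cube eroded twice -> 6^3
})

test_that("anisotropic length scaling prunes orientation-dependently", {
  d <- c(4, 4, 4)
  sp <- c(0.17, 0.17, 0.66)
  vec <- array(NaN, c(d, 3))
  vec[1, 1, 1, ] <- c(0, 0, 1) # scaled norm 0.66
  vec[2, 2, 2, ] <- c(1, 0, 0) # scaled norm 0.17 < 0.5 * 0.66 -> removed
  f <- DirectionField(vec, spacing = sp)
  mk <- MaskVolume(array(TRUE, d), spacing = sp)
  out <- scaleAndPruneLengths(f, mk, 0.5)
  expect_equal(out@vectors[1, 1, 1, ], c(0, 0, 1), tolerance = 1e-12)
  expect_true(all(is.nan(out@vectors[2, 2, 2, ])))
  # isotropic spacing: nothing is removed
  fI <- DirectionField(vec, spacing = c(1, 1, 1))
  outI <- scaleAndPruneLengths(fI, MaskVolume(array(TRUE, d)), 0.5)
  expect_equal(nSupport(outI), 2L)
  # masking first: voxels outside the mask become missing
  mk2 <- MaskVolume(array(FALSE, d), spacing = sp)
  expect_error(scaleAndPruneLengths(f, mk2, 0.5), "empty field")
})

test_that("endpoint pruning uses a simultaneous >= threshold on 26-neighbourhoods", {
  d <- c(5, 5, 5)
  full <- uniform_field(d, c(0, 0, 1))
  out <- pruneEndpoints(full, 18L)
  expect_true(is.finite(out@vectors[3, 3, 3, 1])) # interior: 26 neighbours
  expect_true(all(is.nan(out@vectors[1, 1, 1, ]))) # corner: 7 neighbours
  # a voxel with exactly 18 non-missing neighbours is kept
  sup <- array(FALSE, d)
  sup[2:4, 2:4, 2:4] <- TRUE # centre has 26
  sup[c(2, 4), c(2, 4), 2] <- FALSE
  sup[c(2, 4), c(2, 4), 4] <- FALSE # remove 8 corners -> 18 neighbours
  f <- uniform_field(d, c(0, 0, 1), sup)
  expect_equal(sum(penna3d:::cpp_count_neighbors26(
    as.vector(supportMask(f)), dim(sup))[as.vector(sup)] == 18), 1)
  out2 <- pruneEndpoints(f, 18L)
  expect_true(is.finite(out2@vectors[3, 3, 3, 1]))
  # isolated voxel is removed; pruning never increases support
  iso <- array(FALSE, d); iso[3, 3, 3] <- TRUE
  fi <- uniform_field(d, c(0, 0, 1), iso)
  expect_equal(nSupport(pruneEndpoints(fi, 18L)), 0L)
  expect_lte(nSupport(out2), nSupport(f))
})

test_that("fillMuscle interpolates affine fields exactly and covers the mask", {
  d <- c(12, 12, 12)
  msk <- cuboid_mask(d, c(2, 11), c(2, 11), c(2, 11))
  # support: all mask voxels except an interior hole; y-component affine
  sup <- msk@data
  sup[5:7, 5:7, 5:7] <- FALSE
  idx <- as.matrix(expand.grid(1:d[1], 1:d[2], 1:d[3]))
  lin <- array(0.1 + 0.02 * idx[, 1] + 0.01 * idx[, 2] - 0.015 * idx[, 3], d)
  vec <- array(NaN, c(d, 3))
  vc <- array(NaN, d); vc[sup] <- lin[sup]
  z <- array(NaN, d); z[sup] <- 1
  x0 <- array(NaN, d); x0[sup] <- 0
  vec[, , , 1] <- x0; vec[, , , 2] <- vc; vec[, , , 3] <- z
  f <- DirectionField(vec)
  filled <- fillMuscle(f, msk, SmoothParams())
  expect_equal(nSupport(filled), sum(msk@data)) # exactly the mask
  # hull-interior fill of the y-component is exact (up to re-normalization)
  v656 <- filled@vectors[6, 5, 6, ]
  expect_equal(v656[2] / v656[3], lin[6, 5, 6], tolerance = 1e-6)
  # uniform field fills uniformly
  fu <- uniform_field(d, c(0, 0, 1), sup)
  fillu <- fillMuscle(fu, msk, SmoothParams())
  vm <- matrix(fillu@vectors, ncol = 3)
  vm <- vm[is.finite(vm[, 1]), ]
  expect_equal(max(abs(sweep(vm, 2, c(0, 0, 1)))), 0, tolerance = 1e-6)
  expect_error(fillMuscle(uniform_field(d, c(0, 0, 1),
                                        array(FALSE, d)), msk),
               "insufficient support")
})
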