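make_sweep <- function(nf = 10, d = c(20, 15), px = c(1, 1), step = 0.66,
                       R = diag(3), seed = 1) {
  set.seed(seed)
  frames <- lapply(seq_len(nf), function(i) matrix(runif(prod(d)), d[1], d[2]))
  ts <- (seq_len(nf) - 1) / 30
  poses <- PoseSequence(array(rep(R, nf), c(3, 3, nf)),
                        t(vapply(seq_len(nf) - 1,
                                 function(i) as.numeric(R %*% c(0, 0, i * step)),
                                 numeric(3))), ts)
  list(stack = FrameStack(frames, px, ts), poses = poses)
}

test_that("time offset recovers integer-sample lags and the zero lag", {
  set.seed(7)
  enc <- cumsum(rnorm(60))
  img <- c(rep(enc[1], 3), enc[1:57]) # image lags encoder by 3 samples
  expect_equal(estimateTimeOffset(img, enc, 30), 3 / 30)
  expect_equal(estimateTimeOffset(enc, enc, 30), 0)
  # brute-force lag-scan oracle over a grid of shifts
  for (lag in c(-4L, 2L)) {
    x <- if (lag >= 0) c(rep(enc[1], lag), enc[1:(60 - lag)])
         else c(enc[(1 - lag):60], rep(enc[60], -lag))
    expect_equal(estimateTimeOffset(x, enc, 30), lag / 30)
  }
})

test_that("constant (or purely linear) signals raise a no-variance error", {
  expect_error(estimateTimeOffset(rep(1, 20), rnorm(20), 30), "variance")
  # a pure ramp detrends to zero
  expect_error(estimateTimeOffset(seq_len(20), rnorm(20), 30), "variance")
})

test_that("PCA grid is axis-aligned for an axis-aligned sweep and bounds all corners", {
  sw <- make_sweep()
  g <- defineGrid(sw$stack, sw$poses, c(1, 1, 0.66))
  expect_equal(unname(abs(g@axes)), diag(3), tolerance = 1e-9) # permutation up to sign
  ip <- penna3d:::.interp_poses(sw$poses, sw$stack@timestamps)
  pts <- penna3d:::.frame_corners(sw$stack, ip)
  idx <- sweep(sweep(pts, 2, g@origin, "-") %*% g@axes, 2, g@spacing, "/")
  expect_true(all(idx > -1e-6))
  expect_true(all(sweep(idx, 2, g@dims - 1) < 1e-6))
})

test_that("PCA grid axes follow a rotated sweep", {
  th <- 30 * pi / 180
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  sw <- make_sweep(R = R)
  g <- defineGrid(sw$stack, sw$poses, c(1, 1, 0.66))
  P <- t(g@axes) %*% R
  expect_equal(unname(abs(P)), diag(3), tolerance = 1e-6)
})

test_that("collinear corner clouds are rejected", {
  # frames of width 1 pixel stacked along the same line
  frames <- lapply(1:5, function(i) matrix(runif(1), 1, 1))
  ts <- (0:4) / 30
  poses <- PoseSequence(array(rep(diag(3), 5), c(3, 3, 5)),
                        cbind(0, 0, (0:4) * 0.5), ts)
  st <- FrameStack(frames, c(1, 1), ts)
  expect_error(defineGrid(st, poses, c(1, 1, 0.5)), "degenerate")
})

test_that("a single frame reconstructs bitwise into its slice", {
  sw <- make_sweep(nf = 2)
  g <- defineGrid(sw$stack, sw$poses, c(1, 1, 0.66))
  r <- reconstructVolume(sw$stack, sw$poses, g)
  expect_equal(r$volume@data[, , 1], sw$stack@frames[[1]])
  expect_equal(r$volume@data[, , 2], sw$stack@frames[[2]])
  # parallel frames one voxel apart: no empty voxels between them
  expect_true(all(r$coverage@data))
})

test_that("reconstruction is invariant to a global rigid transform", {
  sw0 <- make_sweep(seed = 3)
  g0 <- defineGrid(sw0$stack, sw0$poses, c(1, 1, 0.66))
  r0 <- reconstructVolume(sw0$stack, sw0$poses, g0)
  th <- 25 * pi / 180
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  sw1 <- make_sweep(seed = 3, R = R)
  g1 <- defineGrid(sw1$stack, sw1$poses, c(1, 1, 0.66))
  r1 <- reconstructVolume(sw1$stack, sw1$poses, g1)
  expect_equal(r1$volume@data, r0$volume@data)
})

test_that("hole filling reaches gaps but never alters pass-1 voxels", {
  # frames 2 voxels apart with sz = 1: every second slice starts empty
  sw <- make_sweep(nf = 5, step = 2)
  g <- defineGrid(sw$stack, sw$poses, c(1, 1, 1))
  r <- reconstructVolume(sw$stack, sw$poses, g, fillRadius = 3L)
  expect_true(all(r$coverage@data))
  # pass-1 voxels are exactly the frame slices
  for (k in 1:5)
    expect_equal(r$volume@data[, , 2 * k - 1], sw$stack@frames[[k]])
  # filled intermediate slice equals one of its neighbours (nearest filled)
  mid <- r$volume@data[, , 2]
  expect_true(all(mid == r$volume@data[, , 1] | mid == r$volume@data[, , 3]))
})

test_that("dense sampling of a smooth scene is recovered from 40 frames", {
  f <- function(w) 100 + 60 * sin(w[, 1] / 4) * cos(w[, 2] / 5) * sin(w[, 3] / 3)
  nf <- 40
  d <- c(24, 18)
  ts <- (seq_len(nf) - 1) / 30
  frames <- lapply(seq_len(nf), function(k) {
    ij <- as.matrix(expand.grid(seq_len(d[1]) - 1, seq_len(d[2]) - 1))
    w <- cbind(ij[, 1], ij[, 2], (k - 1) * 0.8)
    matrix(f(w), d[1], d[2])
  })
  poses <- PoseSequence(array(rep(diag(3), nf), c(3, 3, nf)),
                        cbind(0, 0, (seq_len(nf) - 1) * 0.8), ts)
  st <- FrameStack(frames, c(1, 1), ts)
  g <- defineGrid(st, poses, c(1, 1, 0.8))
  r <- reconstructVolume(st, poses, g)
  idx <- as.matrix(expand.grid(seq_len(g@dims[1]) - 1, seq_len(g@dims[2]) - 1,
                               seq_len(g@dims[3]) - 1))
  w <- sweep(sweep(idx, 2, g@spacing, "*") %*% t(g@axes), 2, g@origin, "+")
  expect_lt(mean(abs(r$volume@data - array(f(w), g@dims))), 0.5)
})

test_that("empty stacks and out-of-grid stacks error", {
  sw <- make_sweep(nf = 2)
  g <- defineGrid(sw$stack, sw$poses, c(1, 1, 0.66))
  far <- PoseSequence(sw$poses@rotations,
                      sw$poses@translations + 1000, sw$poses@timestamps)
  expect_error(reconstructVolume(sw$stack, far, g), "no pixel")
})
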