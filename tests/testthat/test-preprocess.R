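test_that("rescale_intensity maps affinely onto [0, 1]", {
  g <- array(c(10, 12.5, 15, 17.5, 20, 11, 19, 14), dim = c(2, 2, 2))
  r <- rescale_intensity(g)
  expect_equal(r[which(g == 15)], 0.5)
  expect_equal(range(r), c(0, 1))
  expect_equal(rescale_intensity(array(7, dim = c(3, 3, 3))),
               array(0, dim = c(3, 3, 3)))
  idp <- array(seq(0, 1, length.out = 27), dim = c(3, 3, 3))
  expect_equal(rescale_intensity(idp), idp)
})

test_that("median filter matches the exhaustive neighbourhood oracle", {
  set.seed(10)
  g <- array(runif(9^3), dim = c(9, 9, 9))
  expect_identical(median_filter(g, 1), g)
  expect_error(median_filter(g, 4), "odd")
  expect_equal(median_filter(g, 3), oracle_median(g, 3))

  hot <- array(0, dim = c(9, 9, 9)); hot[5, 5, 5] <- 100
  expect_true(all(median_filter(hot, 5) == 0))
})

test_that("median filter and rescale commute with spatial flips", {
  set.seed(11)
  g <- array(runif(7 * 8 * 6), dim = c(7, 8, 6))
  flip <- function(a) a[dim(a)[1]:1, , , drop = FALSE]
  expect_equal(median_filter(flip(g), 3), flip(median_filter(g, 3)))
  expect_equal(rescale_intensity(flip(g)), flip(rescale_intensity(g)))
})

test_that("rolling ball equals the exhaustive opening oracle and preserves peaks", {
  # constant slice -> all zeros
  flat <- array(3, dim = c(12, 12, 2))
  expect_true(all(rolling_ball_subtract(flat, 4, "pixels") == 0))

  # direct comparison against the exhaustive min/max oracle (small radius)
  set.seed(12)
  g <- array(runif(20 * 20 * 2), dim = c(20, 20, 2))
  got <- rolling_ball_subtract(g, 4, "pixels")
  for (z in 1:2) {
    bg <- oracle_ball_opening(g[, , z], 4)
    expect_equal(got[, , z], pmax(g[, , z] - bg, 0), tolerance = 1e-12)
  }

  # small bright disk (diameter << ball radius) on a flat offset:
  # offset removed, amplitude kept within 5%
  sl <- array(0.2, dim = c(41, 41, 1))
  ys <- row(sl[, , 1]); xs <- col(sl[, , 1])
  disk <- (ys - 21)^2 + (xs - 21)^2 <= 2^2
  sl[, , 1][disk] <- sl[, , 1][disk] + 1
  out <- rolling_ball_subtract(sl, 40, "pixels")
  expect_lt(max(out[, , 1][!disk]), 0.05)            # offset removed
  expect_gt(out[21, 21, 1], 0.95)                    # amplitude kept (5%)

  # linear ramp + spots: spot contrast against local surround kept to 10%
  ramp <- array(rep(seq(0, 1, length.out = 41), each = 41),
                dim = c(41, 41, 1))
  spot_centres <- rbind(c(11, 11), c(31, 31))
  sp <- ramp
  for (i in 1:2) {
    dd <- (ys - spot_centres[i, 1])^2 + (xs - spot_centres[i, 2])^2
    sp[, , 1][dd <= 4] <- sp[, , 1][dd <= 4] + 0.8
  }
  out <- rolling_ball_subtract(sp, 40, "pixels")
  for (i in 1:2) {
    yc <- spot_centres[i, 1]; xc <- spot_centres[i, 2]
    dd <- (ys - yc)^2 + (xs - xc)^2
    surround <- out[, , 1][dd > 16 & dd <= 36]
    contrast <- out[yc, xc, 1] - median(surround)
    expect_equal(contrast, 0.8, tolerance = 0.1 * 0.8)
  }

  # unit conversion and the sub-pixel error
  geo <- voxel_geometry(0.5, 1)
  expect_error(rolling_ball_subtract(flat, 0.2, "um", geo), "one pixel")
  expect_error(rolling_ball_subtract(flat, 1, "um"), "geometry")
})

test_that("background subtractions are non-negative and bounded by the input", {
  set.seed(13)
  g <- array(runif(24 * 24 * 8), dim = c(24, 24, 8))
  geo <- voxel_geometry(1, 1)
  for (out in list(rolling_ball_subtract(g, 5, "pixels"),
                   gaussian_background_subtract(g, 12, geo))) {
    expect_gte(min(out), 0)
    expect_true(all(out <= g + 1e-12))
  }
})

test_that("equalize_z flattens depth decay and is idempotent", {
  set.seed(14)
  # bright blobs on every slice, scaled by exp(-z/tau)
  base <- array(0, dim = c(24, 24, 10))
  for (z in 1:10) {
    sl <- matrix(0, 24, 24)
    sl[6:9, 6:9] <- 1
    sl[15:19, 14:18] <- 0.9
    base[, , z] <- (sl + 0.02) * exp(-(z - 0.5) / 6)
  }
  eq <- equalize_z(base)
  rep1 <- attr(eq, "equalize_report")
  expect_false(any(rep1$flagged))
  # robust centres now constant within 2%
  centres <- sapply(1:10, function(z) {
    v <- as.vector(eq[, , z])
    thr <- pseudoislet3d:::otsu_threshold_values(v)
    median(v[v >= thr])
  })
  expect_lt(diff(range(centres)) / max(centres), 0.02)

  # idempotence
  eq2 <- equalize_z(eq)
  expect_equal(as.vector(eq2), as.vector(eq), tolerance = 1e-6)

  # uniform stack unchanged; single-slice identity; flat slice flagged
  u <- array(rep(c(0, 1), each = 8 * 16), dim = c(16, 16, 4))
  expect_equal(as.vector(equalize_z(u)), as.vector(u), tolerance = 1e-6)
  one <- array(runif(25), dim = c(5, 5, 1))
  expect_equal(as.vector(equalize_z(one)), as.vector(one), tolerance = 1e-6)
  fl <- base; fl[, , 3] <- 0.5
  repf <- attr(equalize_z(fl), "equalize_report")
  expect_true(repf$flagged[3])
  expect_equal(repf$scale[3], 1)
})

test_that("gaussian_laplace matches a dense sampled-kernel convolution", {
  expect_true(all(gaussian_laplace(array(5, dim = c(8, 8, 2)), 2) == 0))

  set.seed(15)
  n <- 32
  g <- array(runif(n * n), dim = c(n, n, 1))
  sigma <- 1.2
  got <- gaussian_laplace(g, sigma)
  # oracle: dense 2D convolution with the composed kernel (sampled
  # Gaussian followed by the discrete 5-point Laplacian), evaluated on
  # interior pixels where padding plays no role
  r <- as.integer(ceiling(4 * sigma))
  k1 <- exp(-((-r:r)^2) / (2 * sigma^2)); k1 <- k1 / sum(k1)
  G <- outer(k1, k1)
  m <- 2 * r + 3                     # composed kernel support
  lap <- matrix(0, m, m)
  ctr <- 2:(m - 1)
  lap[ctr, ctr] <- -4 * G
  lap[ctr - 1, ctr] <- lap[ctr - 1, ctr] + G
  lap[ctr + 1, ctr] <- lap[ctr + 1, ctr] + G
  lap[ctr, ctr - 1] <- lap[ctr, ctr - 1] + G
  lap[ctr, ctr + 1] <- lap[ctr, ctr + 1] + G
  rr <- r + 1
  interior <- (rr + 1):(n - rr)
  oracle <- matrix(NA_real_, n, n)
  for (y in interior) for (x in interior) {
    sub <- g[(y - rr):(y + rr), (x - rr):(x + rr), 1]
    oracle[y, x] <- -sigma^2 * sum(sub * lap)
  }
  expect_equal(got[interior, interior, 1],
               oracle[interior, interior], tolerance = 1e-5)
})

test_that("LoG response peaks at a blob of matching scale", {
  ys <- matrix(rep(1:33, 33), 33)
  xs <- t(ys)
  s <- 2
  blob <- exp(-((ys - 17)^2 + (xs - 17)^2) / (2 * s^2))
  resp <- gaussian_laplace(array(blob, dim = c(33, 33, 1)), s)
  expect_equal(which.max(resp[, , 1]),
               which.max(as.vector(blob)))
})

test_that("gaussian background subtraction keeps sharp spots and kills flats", {
  geo <- voxel_geometry(1, 1)
  expect_true(all(gaussian_background_subtract(
    array(2, dim = c(16, 16, 4)), 10, geo) == 0))

  spot <- array(0, dim = c(33, 33, 9))
  spot[17, 17, 5] <- 1
  out <- gaussian_background_subtract(spot, 30, geo)
  expect_gte(out[17, 17, 5], 0.9)

  expect_warning(res <- gaussian_background_subtract(spot, 0.5, geo),
                 "sub-voxel")
  expect_true(all(res == 0))
  expect_error(gaussian_background_subtract(spot, -1, geo), "positive")
})

test_that("the pyramid path agrees with direct convolution for big sigmas", {
  set.seed(16)
  g <- array(runif(40 * 40 * 6), dim = c(40, 40, 6))
  geo <- voxel_geometry(1, 1)
  # sigma 9 voxels triggers the pyramid; compare with the direct separable
  # convolution at the same sigma
  fast <- gaussian_smooth(g, 9, geo)
  # reference: direct separable convolution with the sampled kernel
  k <- exp(-(-36:36)^2 / (2 * 81)); k <- k / sum(k)
  ref <- g
  for (axis in 0:2)
    ref <- array(pseudoislet3d:::conv1_axis_cpp(ref, dim(g), k, axis),
                 dim = dim(g))
  expect_equal(fast, ref, tolerance = 0.02)
  expect_equal(mean(fast), mean(ref), tolerance = 0.005)
})
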