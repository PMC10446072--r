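test_that("global Otsu separates a bimodal grid and matches the exhaustive oracle", {
  set.seed(20)
  v <- c(rep(0, 900), rep(1, 100))
  g <- array(sample(v), dim = c(10, 10, 10))
  b <- threshold_otsu(g, "global")
  expect_equal(mean(b), 0.1)
  expect_true(all(b[g == 1]))

  # shift invariance
  expect_identical(threshold_otsu(g + 5, "global"), b)

  # exhaustive oracle on random bimodal mixtures
  for (s in 1:5) {
    set.seed(s)
    v <- c(rnorm(2000, 0.2, 0.05), rnorm(500, 0.7, 0.08))
    g <- array(v[1:2197], dim = c(13, 13, 13))
    t_oracle <- oracle_otsu(as.vector(g))
    got <- threshold_otsu(g, "global")
    expect_identical(got, array(g >= t_oracle, dim = dim(g)))
  }

  expect_error(threshold_otsu(array(1, dim = c(4, 4, 4)), "global"),
               "constant")
})

test_that("Otsu is invariant to positive affine intensity maps", {
  set.seed(21)
  g <- array(c(rnorm(400, 1, 0.1), rnorm(112, 3, 0.2)), dim = c(8, 8, 8))
  b <- threshold_otsu(g, "global")
  expect_identical(threshold_otsu(2.5 * g + 7, "global"), b)
})

test_that("adaptive Otsu reduces to sensible behaviour on uniform blocks", {
  set.seed(22)
  g <- array(c(rnorm(1500, 0.2, 0.03), rnorm(548, 0.8, 0.03)),
             dim = c(16, 16, 8))
  g <- array(sample(g), dim = dim(g))
  glob <- threshold_otsu(g, "global")
  adap <- threshold_otsu(g, "adaptive", block = 8)
  # same foreground on a well-mixed bimodal grid
  expect_gt(mean(adap == glob), 0.98)
})

test_that("manual thresholding is a plain cutoff", {
  g <- array(c(0, 0, 1, 1, 2, 2, 3, 3), dim = c(2, 2, 2))
  expect_true(all(threshold_manual(g, min(g))))
  expect_true(all(!threshold_manual(g, max(g) + 1)))
  expect_equal(sum(threshold_manual(g, 1.5)), 4)
})

test_that("connected components match the flood-fill oracle", {
  # face-sharing voxels join at any connectivity
  b <- array(FALSE, dim = c(3, 3, 3))
  b[1, 1, 1] <- b[2, 1, 1] <- TRUE
  for (conn in c(6, 18, 26))
    expect_equal(label_components(b, conn)$n_objects, 1)

  # corner-sharing voxels: one object at 26, two at 6
  b <- array(FALSE, dim = c(3, 3, 3))
  b[1, 1, 1] <- b[2, 2, 2] <- TRUE
  expect_equal(label_components(b, 26)$n_objects, 1)
  expect_equal(label_components(b, 6)$n_objects, 2)

  # randomized equivalence with the BFS oracle (all connectivities)
  set.seed(23)
  for (i in 1:30) {
    b <- array(runif(12^3) < 0.35, dim = c(12, 12, 12))
    conn <- sample(c(6, 18, 26), 1)
    got <- label_components(b, conn)$labels
    ora <- oracle_label(b, conn)
    expect_equal(max(got), max(ora))
    expect_true(same_partitioning(got, ora))
  }
})

test_that("size filter applies strict voxel and area cutoffs", {
  g <- voxel_geometry(1, 1)
  # one object of exactly 250 voxels (25 x 10 x 1), strict > removes it
  b <- array(FALSE, dim = c(30, 30, 3))
  b[1:25, 1:10, 2] <- TRUE
  lm <- label_components(b, 26, g)
  expect_equal(size_filter(lm, min_voxels = 250)$n_objects, 0)
  expect_equal(size_filter(lm, min_voxels = 249)$n_objects, 1)
  # area rule keeps objects at the cutoff (250 voxels in one slice = 250 um^2)
  expect_equal(size_filter(lm, min_area = 250)$n_objects, 1)
  expect_equal(size_filter(lm, min_area = 250.5)$n_objects, 0)
  # no-op filter is the identity
  expect_identical(size_filter(lm, 0, 0)$labels, lm$labels)

  # mixed-size fixture against per-object brute-force measurement
  set.seed(24)
  b <- array(runif(18^3) < 0.25, dim = c(18, 18, 18))
  lm <- label_components(b, 6, g)
  st <- table(lm$labels[lm$labels > 0])
  survivors_oracle <- sum(st > 20)
  expect_equal(size_filter(lm, min_voxels = 20)$n_objects, survivors_oracle)
})

test_that("watershed splits fused spheres along the midplane", {
  g <- voxel_geometry(1, 1)
  # single sphere: no spurious split
  one <- spheres_grid(cbind(12, 12, 8), 5, g, c(24, 24, 16)) > 0
  expect_equal(watershed_split(one, 8, g)$n_objects, 1)

  # two fused spheres, 25% centre overlap: split within a voxel of the plane
  r <- 5; overlap <- 0.75 * 2 * r
  cs <- rbind(c(12, 14, 9), c(12 + overlap, 14, 9))
  two <- spheres_grid(cs, r, g, c(30, 28, 18)) > 0
  ws <- watershed_split(two, 8, g)
  expect_equal(ws$n_objects, 2)
  mid_x <- (12 + 12 + overlap) / 2
  for (lb in 1:2) {
    w <- which(ws$labels == lb, arr.ind = TRUE)
    xs <- (w[, 2] - 0.5)  # x positions in um
    # each fragment stays on its side of the midplane within one voxel
    side <- if (mean(xs) < mid_x) max(xs) <= mid_x + 1 else min(xs) >= mid_x - 1
    expect_true(side)
  }

  # three-sphere chain -> 3 objects
  cs <- rbind(c(10, 12, 9), c(10 + overlap, 12, 9), c(10 + 2 * overlap, 12, 9))
  three <- spheres_grid(cs, r, g, c(34, 24, 18)) > 0
  expect_equal(watershed_split(three, 8, g)$n_objects, 3)
})

test_that("watershed never decreases and size filter never increases counts", {
  g <- voxel_geometry(1, 1)
  set.seed(25)
  for (i in 1:8) {
    b <- array(runif(14^3) < 0.3, dim = c(14, 14, 14))
    n0 <- label_components(b, 26, g)$n_objects
    nw <- watershed_split(b, 3, g)$n_objects
    expect_gte(nw, n0)
    lm <- label_components(b, 26, g)
    expect_lte(size_filter(lm, min_voxels = sample(0:5, 1))$n_objects, n0)
  }
})

test_that("spot detection recovers rendered nuclei exactly in the clean regime", {
  g <- voxel_geometry(1, 1)
  expect_equal(nrow(detect_spots(array(0, dim = c(10, 10, 10)), 6,
                                 geometry = g)), 0)

  centres <- rbind(c(10, 10, 10), c(24, 10, 10), c(10, 24, 12),
                   c(24, 24, 14), c(17, 17, 22))
  grid <- spheres_grid(centres, 3, g, c(34, 34, 30))
  spots <- detect_spots(grid, 6, geometry = g)
  expect_equal(nrow(spots), 5)
  got <- spots[order(spots$centroid_x, spots$centroid_y), ]
  for (i in seq_len(5)) {
    d <- sqrt((spots$centroid_x - centres[i, 1])^2 +
              (spots$centroid_y - centres[i, 2])^2 +
              (spots$centroid_z - centres[i, 3])^2)
    expect_lte(min(d), sqrt(3))   # within one voxel of the true centre
  }

  # a quality threshold above the top response suppresses everything
  high <- max(spots$mean_intensity) * 1.01
  expect_equal(nrow(detect_spots(grid, 6, high, g)), 0)
})

test_that("surface detection finds separated cells and is deterministic", {
  g <- voxel_geometry(1, 1)
  centres <- rbind(c(10, 10, 9), c(24, 22, 12))
  grid <- spheres_grid(centres, 5, g, c(34, 34, 22))
  lm <- detect_surfaces(grid, 0.6, 16, NULL, g)
  expect_equal(lm$n_objects, 2)
  lm2 <- detect_surfaces(grid, 0.6, 16, NULL, g)
  expect_identical(lm$labels, lm2$labels)
  empty <- detect_surfaces(array(0, dim = c(10, 10, 6)), 0.6, 16, NULL, g)
  expect_equal(empty$n_objects, 0)
})

test_that("object measurements equal brute-force accumulation", {
  g <- voxel_geometry(0.5, 2)
  lab <- array(0L, dim = c(6, 6, 4))
  lab[2, 3, 4] <- 1L
  lm <- label_map(lab, g)
  tab <- measure_objects(lm, array(1, dim = dim(lab)), "nuclei")
  # voxel (y=2, x=3, z=4) centre in um
  expect_equal(tab$centroid_x, (3 - 0.5) * 0.5)
  expect_equal(tab$centroid_y, (2 - 0.5) * 0.5)
  expect_equal(tab$centroid_z, (4 - 0.5) * 2)
  expect_equal(tab$volume, 0.5 * 0.5 * 2)

  lab[1:2, 1:2, 1:2] <- 2L
  lm <- label_map(lab, g)
  tab <- measure_objects(lm, array(1, dim = dim(lab)), "nuclei")
  expect_equal(tab$volume[2], 8 * voxel_volume(g))
  expect_equal(tab$max_slice_area[2], 4 * 0.25)

  # random fixture: all measures vs direct per-voxel accumulation
  set.seed(26)
  b <- array(runif(10^3) < 0.3, dim = c(10, 10, 10))
  intens <- array(runif(10^3) + 0.1, dim = c(10, 10, 10))
  lm <- label_components(b, 26, g)
  tab <- measure_objects(lm, intens, "nuclei")
  for (k in seq_len(lm$n_objects)) {
    w <- which(lm$labels == k, arr.ind = TRUE)
    ww <- intens[lm$labels == k]
    expect_equal(tab$voxel_count[k], nrow(w))
    expect_equal(tab$mean_intensity[k], mean(ww))
    expect_equal(tab$centroid_x[k],
                 (sum((w[, 2] - 0.5) * ww) / sum(ww)) * 0.5 + 0)
    expect_equal(tab$max_slice_area[k],
                 max(table(w[, 3])) * 0.25)
  }
})
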