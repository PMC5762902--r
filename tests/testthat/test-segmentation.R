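test_that("k = 1 puts every tissue pixel in one segment with the pooled mean", {
  tc <- two_class_cube(n = 6, seed = 1)
  segs <- kmeanspp_joint(list(tc$cube), seg_config(1, seed = 1))
  s <- segs[[1]]
  expect_true(all(s$labels == 1L))
  fit <- ftirguide:::kmeanspp_fit(tc$cube$data, 1, seed = 1)
  expect_equal(as.numeric(fit$centers), colMeans(tc$cube$data))
})

test_that("joint clustering gives the same IDX to the same class in every section", {
  skip_if_not_installed("mclust")
  c1 <- two_class_cube(n = 8, seed = 1, section_id = "a")
  c2 <- two_class_cube(n = 8, seed = 2, section_id = "b")
  segs <- kmeanspp_joint(list(c1$cube, c2$cube), seg_config(2, seed = 7))
  l1 <- as.integer(t(segs[["a"]]$labels))
  l2 <- as.integer(t(segs[["b"]]$labels))
  expect_equal(mclust::adjustedRandIndex(l1, c1$labels), 1.0)
  expect_equal(mclust::adjustedRandIndex(l2, c2$labels), 1.0)
  # class A pixels (left half) carry one IDX consistently across sections
  expect_equal(unique(l1[c1$labels == 1]), unique(l2[c2$labels == 1]))
})

test_that("3-class phantom is recovered at ARI >= 0.95 under the stated noise", {
  skip_if_not_installed("mclust")
  ph <- generate_phantom(phantom_spec(seed = 21))
  pp <- ftir_preprocess(ph$cube)
  segs <- kmeanspp_joint(list(pp), seg_config(3, seed = 1))
  on <- segs[[1]]$labels > 0 & ph$truth_ftir$labels > 0
  ari <- mclust::adjustedRandIndex(segs[[1]]$labels[on],
                                   ph$truth_ftir$labels[on])
  expect_gte(ari, 0.95)
})

test_that("joint clustering is invariant to section ordering and bit-repeatable", {
  c1 <- two_class_cube(n = 6, seed = 3, section_id = "a")
  c2 <- two_class_cube(n = 6, seed = 4, section_id = "b")
  cfg <- seg_config(2, seed = 5)
  fwd <- kmeanspp_joint(list(c1$cube, c2$cube), cfg)
  rev <- kmeanspp_joint(list(c2$cube, c1$cube), cfg)
  expect_identical(fwd[["a"]]$labels, rev[["a"]]$labels)
  expect_identical(fwd[["b"]]$labels, rev[["b"]]$labels)
  again <- kmeanspp_joint(list(c1$cube, c2$cube), cfg)
  expect_identical(fwd[["a"]]$labels, again[["a"]]$labels)
})

test_that("axis mismatch and oversized k are rejected", {
  c1 <- two_class_cube(n = 4, n_ch = 20, seed = 1, section_id = "a")
  c2 <- two_class_cube(n = 4, n_ch = 21, seed = 2, section_id = "b")
  expect_error(kmeanspp_joint(list(c1$cube, c2$cube), seg_config(2)),
               "axis")
  expect_error(kmeanspp_joint(list(c1$cube), seg_config(100, seed = 1)),
               "pooled")
})

test_that("tissue shape extraction is contrast-inversion invariant", {
  dm <- disk_mask(24)
  img <- dm$values * 1 + withr::with_seed(2, matrix(rnorm(576, 0, 0.02), 24))
  m1 <- tissue_shape_mask(img, pixel_size = 25)
  expect_gt(mean(m1$values == dm$values), 0.99)
  m2 <- tissue_shape_mask(1 - img, pixel_size = 25) # inverted contrast
  expect_identical(m2$values, m1$values)
  expect_error(tissue_shape_mask(matrix(1, 8, 8)), "constant")
})

test_that("spatially aware clustering: radius 0 is plain k-means++, smoothing despeckles", {
  # checkerboard-ish two-class MSI with speckle noise
  n <- 12
  g <- pixel_grid(n, n, 75)
  ctr <- grid_centers(g)
  cls <- ifelse(ctr$col < n / 2, 0, 1)
  withr::with_seed(11, {
    speckle <- sample(seq_len(n * n), 25) # flip some pixels' class
    cls[speckle] <- 1 - cls[speckle]
    ints <- cbind(cls * 2 + rnorm(n * n, 0, 0.3),
                  (1 - cls) * 2 + rnorm(n * n, 0, 0.3))
  })
  ints <- ints - min(ints)
  ds <- msi_dataset(g, ctr$pixel, mode = "continuous", mz_axis = c(500, 600),
                    intensities = ints)
  cfg0 <- seg_config(2, seed = 3, spatial_radius = 0)
  plain <- spatially_aware_cluster(ds, cfg0)
  fit <- ftirguide:::kmeanspp_fit(ints, 2, seed = 3, n_init = cfg0$n_init,
                                  max_iter = cfg0$max_iter)
  can <- ftirguide:::canonicalize_labels(fit$cluster, fit$centers)
  expect_identical(as.integer(t(plain$labels)), can$cluster)

  aware <- spatially_aware_cluster(ds, seg_config(2, seed = 3,
                                                  spatial_radius = 3))
  n_comp <- function(seg) {
    sum(vapply(1:2, function(i) {
      max(EBImage::bwlabel(seg$labels == i))
    }, numeric(1)))
  }
  expect_lt(n_comp(aware), n_comp(plain))
})

test_that("uniform data stays a single effective cluster under any radius", {
  g <- pixel_grid(6, 6, 75)
  ctr <- grid_centers(g)
  ints <- matrix(1, 36, 3) + withr::with_seed(5, matrix(rnorm(108, 0, 1e-6), 36))
  ds <- msi_dataset(g, ctr$pixel, mode = "continuous",
                    mz_axis = c(500, 600, 700), intensities = ints)
  for (r in c(0, 2)) {
    seg <- spatially_aware_cluster(ds, seg_config(1, seed = 1,
                                                  spatial_radius = r))
    expect_true(all(seg$labels == 1L))
  }
})

test_that("neighborhood smoothing preserves channel means away from borders", {
  n <- 16
  g <- pixel_grid(n, n, 75)
  ctr <- grid_centers(g)
  ints <- matrix(2, n * n, 2)
  # varying pixels at least 2*radius from the border, so every destination
  # they reach still has a complete (untruncated) kernel
  interior <- ctr$row >= 6 & ctr$row <= 9 & ctr$col >= 6 & ctr$col <= 9
  ints[interior, ] <- withr::with_seed(6, matrix(runif(sum(interior) * 2, 0, 4),
                                                 sum(interior)))
  ds <- msi_dataset(g, ctr$pixel, mode = "continuous", mz_axis = c(1, 2),
                    intensities = ints)
  sm <- ftirguide:::smooth_features(ds, radius = 3, sigma = 1.5)
  expect_equal(colMeans(sm), colMeans(ints), tolerance = 1e-6)
})

test_that("segment contours trace pixel boundaries with exact areas", {
  g <- pixel_grid(4, 4, 25)

  one <- matrix(0L, 4, 4); one[1, 1] <- 1L
  cc <- segment_contour(segment_map(g, one, 1), 1)
  expect_equal(length(unique(cc$ring)), 1)
  expect_equal(sum(contour_area(cc)$area), 625)

  block <- matrix(0L, 4, 4); block[2:3, 2:3] <- 1L
  cb <- segment_contour(segment_map(g, block, 1), 1)
  expect_equal(length(unique(cb$ring)), 1)
  expect_equal(sum(contour_area(cb)$area), 2500)

  diag2 <- matrix(0L, 4, 4); diag2[1, 1] <- 1L; diag2[2, 2] <- 1L
  cd <- segment_contour(segment_map(g, diag2, 1), 1)
  expect_equal(length(unique(cd$ring)), 2)
  expect_equal(sum(contour_area(cd)$area), 2 * 625)
})

test_that("contour area identity holds for arbitrary masks (with holes)", {
  withr::with_seed(13, {
    for (i in 1:5) {
      m <- random_mask(10, seed = 100 + i, p = 0.5, pixel_size = 25)
      if (!any(m$values)) next
      cc <- segment_contour(m)
      expect_equal(sum(contour_area(cc)$area), sum(m$values) * 625)
    }
  })
})
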