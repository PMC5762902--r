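test_that("pixel grid physical mapping is invertible on-grid", {
  g <- pixel_grid(7, 11, 6.25, origin = c(100, -50))
  ctr <- grid_centers(g)
  back <- phys_to_grid(g, ctr$x, ctr$y)
  expect_equal(back[, "r"], as.numeric(ctr$row))
  expect_equal(back[, "c"], as.numeric(ctr$col))
  expect_equal(grid_to_phys(g, 1, 2), cbind(x = 100 + 2 * 6.25,
                                            y = -50 + 1 * 6.25))
})

test_that("imzML continuous round-trip preserves spectra and coordinates", {
  ds <- random_msi(2, 2, n_mz = 6, seed = 7)
  path <- file.path(withr::local_tempdir(), "t.imzML")
  write_imzml(ds, path)
  rd <- read_imzml(path)
  expect_equal(rd$mode, "continuous")
  expect_identical(rd$pixel_idx, ds$pixel_idx)
  expect_identical(rd$mz_axis, ds$mz_axis)
  expect_identical(rd$intensities, ds$intensities)
  expect_equal(rd$grid$pixel_size, ds$grid$pixel_size)
})

test_that("imzML processed round-trip keeps per-pixel centroids, no shared axis", {
  ds <- random_msi_processed(seed = 3)
  path <- file.path(withr::local_tempdir(), "p.imzML")
  write_imzml(ds, path)
  rd <- read_imzml(path)
  expect_equal(rd$mode, "processed")
  expect_null(rd$mz_axis)
  for (i in seq_along(ds$peaks)) {
    expect_identical(rd$peaks[[i]]$mz, ds$peaks[[i]]$mz)
    expect_identical(rd$peaks[[i]]$intensity, ds$peaks[[i]]$intensity)
  }
})

test_that("a missing coordinate stays an absent pixel, not a zero spectrum", {
  ds <- random_msi(2, 2, n_mz = 4, seed = 2, drop_pixels = 2L)
  expect_equal(length(ds$pixel_idx), 3)
  path <- file.path(withr::local_tempdir(), "hole.imzML")
  write_imzml(ds, path)
  rd <- read_imzml(path)
  expect_equal(length(rd$pixel_idx), 3)
  expect_false(2L %in% rd$pixel_idx)
})

test_that("one-pixel dataset round-trips and missing ibd errors", {
  ds <- random_msi(1, 1, n_mz = 3, seed = 5)
  path <- file.path(withr::local_tempdir(), "one.imzML")
  write_imzml(ds, path)
  expect_identical(read_imzml(path)$intensities, ds$intensities)
  file.remove(sub("imzML$", "ibd", path))
  expect_error(read_imzml(path), "ibd")
})

test_that("pyimzml reads our imzML the same way (external oracle)", {
  ds <- random_msi(2, 3, n_mz = 5, seed = 11)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "oracle.imzML")
  write_imzml(ds, path)
  script <- file.path(dir, "read.py")
  writeLines(c(
    "import sys, json",
    "from pyimzml.ImzMLParser import ImzMLParser",
    "p = ImzMLParser(sys.argv[1])",
    "out = []",
    "for i, (x, y, z) in enumerate(p.coordinates):",
    "    mz, ints = p.getspectrum(i)",
    "    out.append({'x': int(x), 'y': int(y),",
    "                'mz': [float(v) for v in mz],",
    "                'ints': [float(v) for v in ints]})",
    "print(json.dumps(out))"
  ), script)
  res <- suppressWarnings(
    system2("python", c(script, path), stdout = TRUE, stderr = FALSE)
  )
  skip_if(length(res) == 0 || is.null(attr(res, "status")) == FALSE &&
            attr(res, "status") != 0, "python/pyimzml unavailable")
  j <- jsonlite::fromJSON(paste(res, collapse = ""), simplifyVector = FALSE)
  expect_equal(length(j), length(ds$pixel_idx))
  for (i in seq_along(j)) {
    px <- (j[[i]]$y - 1) * ds$grid$n_cols + (j[[i]]$x - 1)
    r <- match(px, ds$pixel_idx)
    expect_equal(unlist(j[[i]]$mz), ds$mz_axis)
    expect_equal(unlist(j[[i]]$ints), unname(ds$intensities[r, ]))
  }
})

test_that("cube CSV and ENVI round-trips are identities; ascending axes flip", {
  wn_desc <- seq(1800, 1000, by = -50)
  g <- pixel_grid(3, 4, 25)
  data <- matrix(rnorm(12 * length(wn_desc)), 12)
  cube <- hyper_cube(g, wn_desc, data)
  dir <- withr::local_tempdir()

  csv <- file.path(dir, "cube.csv")
  write_cube(cube, csv)
  rd <- read_cube(csv, pixel_size = 25)
  expect_equal(rd$wavenumbers, cube$wavenumbers)
  expect_equal(rd$data, cube$data, tolerance = 1e-10)

  envi <- file.path(dir, "cube.dat")
  write_cube(cube, envi)
  rd2 <- read_cube(envi)
  expect_identical(rd2$wavenumbers, cube$wavenumbers)
  expect_identical(rd2$data, cube$data)
  expect_equal(rd2$grid$pixel_size, 25)

  # ascending axis on disk: returned descending with data reversed to match
  asc <- hyper_cube(g, rev(wn_desc), data[, rev(seq_along(wn_desc))])
  expect_equal(asc$wavenumbers, wn_desc)
  expect_equal(asc$data, data)
})

test_that("1x1 cube loads with a 1x1 grid", {
  cube <- hyper_cube(pixel_grid(1, 1, 25), seq(1500, 1100, by = -100),
                     matrix(1:5, 1))
  p <- file.path(withr::local_tempdir(), "tiny.csv")
  write_cube(cube, p)
  rd <- read_cube(p, pixel_size = 25)
  expect_equal(rd$grid$n_rows, 1L)
  expect_equal(rd$grid$n_cols, 1L)
  expect_equal(as.numeric(rd$data), 1:5) # channel order follows the axis
})

test_that("mask round-trips losslessly; PNG is strictly two-valued", {
  m <- random_mask(12, seed = 4)
  dir <- withr::local_tempdir()
  for (ext in c("png", "csv")) {
    p <- file.path(dir, paste0("m.", ext))
    write_mask(m, p)
    rd <- read_mask(p, pixel_size = 1)
    expect_identical(rd$values, m$values)
  }
  raw_img <- png::readPNG(file.path(dir, "m.png"))
  expect_true(all(raw_img %in% c(0, 1))) # 8-bit 0 or 255 on disk

  empty <- binary_mask(pixel_grid(4, 4, 1), matrix(FALSE, 4, 4))
  p <- file.path(dir, "empty.png")
  write_mask(empty, p)
  expect_identical(read_mask(p)$values, empty$values)
})

test_that("segment map CSV round-trip preserves labels", {
  seg <- segment_map(pixel_grid(4, 5, 25),
                     matrix(sample(0:3, 20, TRUE), 4, 5), k = 3)
  p <- file.path(withr::local_tempdir(), "seg.csv")
  write_segment_map(seg, p)
  rd <- read_segment_map(p, k = 3, pixel_size = 25)
  expect_identical(rd$labels, seg$labels)
})

test_that("feature table CSV round-trips; empty table is header-only", {
  t <- ranked_features(mz = 500 + 1:10, criterion = rev(1:10) / 10,
                       direction = rep(c("up", "down"), 5), segment_id = 2L)
  p <- file.path(withr::local_tempdir(), "ft.csv")
  write_feature_table(t, p)
  expect_equal(length(readLines(p)), 11) # header + 10 rows
  rd <- read_feature_table(p)
  expect_equal(rd$mz, t$mz)
  expect_equal(rd$rank, t$rank)
  expect_equal(rd$criterion, t$criterion)

  empty <- ranked_features(numeric(0), numeric(0), character(0), 1L)
  write_feature_table(empty, p)
  expect_equal(length(readLines(p)), 1)
  expect_equal(nrow(read_feature_table(p)), 0)
})

test_that("transform JSON round-trips", {
  tr <- similarity_transform(12.5, -3.25, 7.5, 1.05, center = c(100, 200))
  p <- file.path(withr::local_tempdir(), "t.json")
  write_transform(tr, p)
  rd <- read_transform(p)
  expect_equal(rd$tx, tr$tx)
  expect_equal(rd$theta, tr$theta)
  expect_equal(rd$s, tr$s)
  expect_equal(rd$center, tr$center)
})

test_that("container invariants are enforced", {
  g <- pixel_grid(2, 2, 25)
  expect_error(msi_dataset(g, 0:3, mode = "continuous",
                           mz_axis = c(2, 1),
                           intensities = matrix(1, 4, 2)), "increasing")
  expect_error(msi_dataset(g, 0:4, mode = "continuous", mz_axis = 1,
                           intensities = matrix(1, 5, 1)), "range")
  expect_error(hyper_cube(g, c(1500, 1600, 1400), matrix(1, 4, 3)),
               "monotonic")
  expect_error(binary_mask(g, matrix(TRUE, 3, 2)), "shape")
  expect_error(segment_map(g, matrix(5L, 2, 2), k = 3), "0..k")
})
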