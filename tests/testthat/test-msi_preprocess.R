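test_that("TIC normalization scales to the target and preserves ratios", {
  cfg <- msi_config(tic_target = 1)
  expect_equal(tic_normalize(c(2, 3, 5), cfg), c(0.2, 0.3, 0.5))
  withr::with_seed(4, {
    for (i in 1:5) {
      y <- rexp(50)
      z <- tic_normalize(y, cfg)
      expect_equal(sum(z), 1)
      expect_equal(z / z[1], y / y[1], tolerance = 1e-12)
    }
  })
  expect_error(tic_normalize(rep(0, 5), cfg), "TIC")
})

test_that("top-hat baseline: hand-evaluated opening, idempotence, constants", {
  cfg1 <- msi_config(tophat_halfwidth = 1)
  r <- tophat_baseline(c(0, 0, 5, 0, 0), cfg1)
  expect_equal(r$baseline, rep(0, 5)) # erosion kills the spike
  expect_equal(r$corrected, c(0, 0, 5, 0, 0))

  const <- rep(4.2, 30)
  rc <- tophat_baseline(const, msi_config(tophat_halfwidth = 5))
  expect_equal(rc$baseline, const)
  expect_equal(rc$corrected, rep(0, 30))

  withr::with_seed(6, {
    y <- abs(rnorm(300)) + 5 * exp(-(seq_len(300) - 150)^2 / 18) +
      seq_len(300) / 100
    cfg <- msi_config(tophat_halfwidth = 20)
    once <- tophat_baseline(y, cfg)$corrected
    twice <- tophat_baseline(once, cfg)$corrected
    expect_equal(twice, once, tolerance = 1e-12)
    expect_true(all(once >= 0)) # opening is anti-extensive
  })
})

test_that("supersmoother noise curve: exact on lines, ~0.8 sigma on white noise", {
  cfg <- msi_config()
  i <- seq_len(500)
  line <- 2 + 0.01 * i
  expect_equal(supersmoother_noise(line, cfg), line, tolerance = 1e-6)

  const <- rep(3, 200)
  expect_equal(supersmoother_noise(const, cfg), const, tolerance = 1e-8)

  withr::with_seed(10, {
    y <- abs(rnorm(1000, sd = 2)) # half-normal, like corrected noise
    curve <- supersmoother_noise(y, cfg)
    m <- mean(abs(y - curve))
    # E|N(0, s)| = 0.798 s; the curve tracks the local mean, so the mean
    # absolute residual sits between 0.6 and 0.9 of the underlying sd
    resid_sd <- sqrt(2 * (1 - 2 / pi)) * 2 # sd of half-normal
    expect_gt(m / 2, 0.4)
    expect_lt(m / 2, 0.9)
  })

  expect_warning(supersmoother_noise(c(1, 2, 3), cfg), "linear")
})

test_that("peak picking finds planted peaks and nothing on flat spectra", {
  cfg <- msi_config(snr_threshold = 3)
  expect_equal(nrow(pick_peaks(rep(5, 100), cfg = cfg)), 0)

  # noise floor 20 (the supersmoother reference), apex at 10x that floor;
  # peaks much narrower than the smallest smoother span
  n <- 1000
  i <- seq_len(n)
  withr::with_seed(3, noise <- 20 + rnorm(n, sd = 1))
  apex_pos <- 500
  y <- noise + 200 * exp(-(i - apex_pos)^2 / (2 * 3^2))
  pk <- pick_peaks(y, cfg = cfg)
  expect_equal(nrow(pk), 1)
  expect_lte(abs(pk$mz[1] - apex_pos), 1)
  expect_gte(pk$snr[1], 3)

  y2 <- noise + 200 * exp(-(i - 300)^2 / (2 * 3^2)) +
    200 * exp(-(i - 700)^2 / (2 * 3^2))
  pk2 <- pick_peaks(y2, cfg = cfg)
  expect_equal(nrow(pk2), 2)
  expect_equal(sort(round(pk2$mz)), c(300, 700), tolerance = 1)
})

test_that("plateau ties resolve to the leftmost channel", {
  y <- c(0, 0, 4, 4, 4, 0, 0)
  pk <- pick_peaks(y, noise = rep(1, 7), cfg = msi_config(snr_threshold = 3))
  expect_equal(pk$mz, 3)
})

test_that("binning splits at gaps, respects tolerance, is pixel-order invariant", {
  cfg <- msi_config(bin_tolerance = 0.05)
  pk <- list(
    data.frame(mz = c(500.00, 500.50), intensity = c(1, 2)),
    data.frame(mz = c(500.01), intensity = c(3)),
    data.frame(mz = numeric(0), intensity = numeric(0))
  )
  b <- bin_peaks(pk, cfg)
  expect_length(b$mz_axis, 2)
  expect_equal(b$mz_axis, c(mean(c(500.00, 500.01)), 500.5))
  expect_equal(b$intensities[3, ], c(0, 0)) # empty pixel -> all-zero row
  expect_equal(b$intensities[1, ], c(1, 2))
  expect_equal(b$intensities[2, ], c(3, 0))

  # identical centroids across pixels: one bin per centroid
  pk2 <- rep(list(data.frame(mz = c(400, 500, 600), intensity = 1:3)), 4)
  b2 <- bin_peaks(pk2, cfg)
  expect_equal(b2$mz_axis, c(400, 500, 600))

  # permuting pixels permutes rows, nothing else
  perm <- c(2, 3, 1)
  bp <- bin_peaks(pk[perm], cfg)
  expect_equal(bp$mz_axis, b$mz_axis)
  expect_equal(bp$intensities, b$intensities[perm, ])
})

test_that("a bin never grows wider than the tolerance", {
  cfg <- msi_config(bin_tolerance = 0.1)
  # centroid chain with 0.04 gaps: single-linkage would fuse them all
  pk <- list(data.frame(mz = 500 + 0.04 * 0:9, intensity = rep(1, 10)))
  b <- bin_peaks(pk, cfg)
  u <- 500 + 0.04 * 0:9
  for (bin in seq_along(b$mz_axis)) {
    members <- u[abs(u - b$mz_axis[bin]) == min(abs(outer(u, b$mz_axis, "-")[, bin]))]
  }
  # reconstruct widths from the assignment helper directly
  ids <- ftirguide:::assign_bins(u, function(mz) 0.1)
  widths <- vapply(split(u, ids), function(g) diff(range(g)), numeric(1))
  expect_true(all(widths <= 0.1 + 1e-12))
})

test_that("planted peaks are recovered at recall >= 0.95 and FDR <= 0.05", {
  cfg <- msi_config(tophat_halfwidth = 75, snr_threshold = 3)
  n <- 2000
  i <- seq_len(n)
  true_pos <- seq(100, 1900, by = 100) # 19 peaks, > 4 sigma apart
  sigma <- 1
  # noise reference the pipeline will see: baseline-corrected half-envelope
  noise_ref <- sigma * qnorm(1 - 1 / (2 * (2 * cfg$tophat_halfwidth + 1)))
  apex <- 10 * noise_ref # planted SNR 10
  recalls <- fdrs <- numeric(20)
  for (s in 1:20) {
    y <- withr::with_seed(400 + s, {
      base <- 20 + i / 200 + rnorm(n, sd = sigma)
      for (p in true_pos) base <- base + apex * exp(-(i - p)^2 / (2 * 3^2))
      base
    })
    corr <- tophat_baseline(y, cfg)$corrected
    pk <- pick_peaks(corr, cfg = cfg)
    hit <- vapply(true_pos, function(p) any(abs(pk$mz - p) <= 2), TRUE)
    recalls[s] <- mean(hit)
    fdrs[s] <- if (nrow(pk)) {
      mean(vapply(pk$mz, function(m) all(abs(true_pos - m) > 2), TRUE))
    } else 0
  }
  expect_gte(mean(recalls), 0.95)
  expect_lte(mean(fdrs), 0.05)
})

test_that("the dataset-level pipeline drops zero-TIC pixels and bins the rest", {
  ds <- random_msi(3, 3, n_mz = 50, seed = 12)
  ds$intensities[5, ] <- 0
  expect_warning(binned <- msi_preprocess(ds, msi_config(tophat_halfwidth = 5)),
                 "zero-TIC")
  expect_equal(length(binned$pixel_idx), 8)
  expect_equal(binned$mode, "continuous")
})
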