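# independent dense-matrix AsLS oracle: direct solve of the penalized
# weighted least squares at each reweighting step
asls_oracle <- function(y, lambda, p, iters) {
  n <- length(y)
  D <- diff(diag(n), differences = 2)
  P <- lambda * t(D) %*% D
  w <- rep(1, n)
  z <- y
  for (it in seq_len(iters)) {
    z <- solve(P + diag(w), w * y)
    w_new <- ifelse(y > z, p, 1 - p)
    if (identical(w_new, w)) break
    w <- w_new
  }
  as.numeric(z)
}

test_that("AsLS reproduces constant and affine spectra exactly", {
  cfg <- ftir_config()
  const <- rep(3.7, 50)
  r <- asls_baseline(const, cfg)
  expect_lt(max(abs(r$baseline - 3.7)), 1e-8)
  expect_lt(max(abs(r$corrected)), 1e-8)

  line <- 2 + 0.05 * seq_len(80)
  r2 <- asls_baseline(line, cfg)
  expect_lt(max(abs(r2$corrected)), 1e-8)
})

test_that("AsLS matches the dense linear-algebra oracle and tracks under a peak", {
  cfg <- ftir_config(asls_lambda = 1e5, asls_p = 0.001)
  i <- seq_len(200)
  ramp <- 0.5 + 0.01 * i
  peak <- exp(-(i - 100)^2 / (2 * 3^2))
  y <- ramp + peak
  r <- asls_baseline(y, cfg)
  oracle <- asls_oracle(y, 1e5, 0.001, cfg$asls_iters)
  expect_equal(r$baseline, oracle, tolerance = 1e-9)
  expect_gte(r$corrected[100], 0.9) # apex survives
  off <- abs(i - 100) > 15
  expect_lte(max(abs(r$corrected[off])), 0.05) # baseline hugged elsewhere
  expect_error(asls_baseline(c(1, NA, 2, 3)), "finite")
})

test_that("Savitzky-Golay derivative is exact on low-order polynomials", {
  cfg <- ftir_config(deriv_window = 9, deriv_polyorder = 2)
  wn <- seq(1800, 1000, by = -4)
  interior <- 5:(length(wn) - 4)

  expect_lt(max(abs(first_derivative(rep(2, length(wn)), wn, cfg))), 1e-12)

  line <- 3 + 0.02 * wn
  d <- first_derivative(line, wn, cfg)
  expect_equal(d[interior], rep(0.02, length(interior)), tolerance = 1e-10)

  quad <- 1 + 0.01 * wn + 2e-5 * wn^2
  dq <- first_derivative(quad, wn, cfg)
  expect_equal(dq[interior], (0.01 + 4e-5 * wn)[interior], tolerance = 1e-8)
})

test_that("SNV is exact on the textbook example and scale/offset invariant", {
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1))
  withr::with_seed(42, {
    for (i in 1:10) {
      x <- rnorm(30, sd = runif(1, 0.1, 10))
      s <- snv(x)
      expect_lt(abs(mean(s)), 1e-12)
      expect_lt(abs(sd(s) - 1), 1e-12)
      a <- runif(1, 0.1, 5); b <- rnorm(1)
      expect_equal(snv(a * x + b), s, tolerance = 1e-10)
    }
  })
  expect_error(snv(rep(1, 10)), "zero-variance")
})

test_that("window selection equals a brute-force channel scan", {
  wn <- seq(4000, 650, by = -2)
  cube <- hyper_cube(pixel_grid(2, 2, 25), wn,
                     matrix(rnorm(4 * length(wn)), 4))
  cfg <- ftir_config()
  out <- select_windows(cube, cfg)
  keep <- vapply(wn, function(w) {
    (w <= 3100 && w >= 2900) || (w <= 1800 && w >= 950)
  }, TRUE)
  expect_equal(length(out$wavenumbers), sum(keep))
  expect_identical(out$wavenumbers, wn[keep])
  expect_identical(out$data, cube$data[, keep])

  whole <- select_windows(cube, ftir_config(windows = list(c(4000, 650))))
  expect_identical(whole$data, cube$data)
  expect_error(select_windows(cube, ftir_config(windows = list(c(5000, 4500)))),
               "no channels")
})

test_that("TV denoising: identity at weight 0, noise reduction, weight monotonicity", {
  g <- pixel_grid(24, 24, 25)
  wn <- c(1700, 1600)
  clean_img <- matrix(0, 24, 24)
  clean_img[, 13:24] <- 1
  clean <- as.numeric(t(clean_img))
  noisy <- withr::with_seed(9, clean + rnorm(576, sd = 0.1))
  cube <- hyper_cube(g, wn, cbind(noisy, noisy))

  expect_identical(epd_denoise(cube, ftir_config(epd_weight = 0)), cube)

  den <- epd_denoise(cube, ftir_config(epd_weight = 0.1))
  mse_before <- mean((noisy - clean)^2)
  mse_after <- mean((den$data[, 1] - clean)^2)
  expect_lt(mse_after, mse_before)

  const_cube <- hyper_cube(g, wn, matrix(2, 576, 2))
  expect_equal(epd_denoise(const_cube, ftir_config(epd_weight = 0.2))$data,
               const_cube$data, tolerance = 1e-8)

  # shrinking weight moves the output monotonically toward the input
  dev <- vapply(c(0.2, 0.1, 0.05, 0.01), function(w) {
    d <- epd_denoise(cube, ftir_config(epd_weight = w))
    sqrt(mean((d$data[, 1] - noisy)^2))
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
})

test_that("background removal finds a planted disk and guards all-tissue cubes", {
  g <- pixel_grid(24, 24, 25)
  wn <- seq(1800, 1000, by = -20)
  dm <- disk_mask(24)
  tissue_vec <- as.logical(t(dm$values))
  spec_t <- exp(-(wn - 1650)^2 / (2 * 30^2))
  data <- withr::with_seed(3, {
    outer(as.numeric(tissue_vec), spec_t) +
      matrix(rnorm(576 * length(wn), sd = 0.01), 576)
  })
  cube <- hyper_cube(g, wn, data)
  rb <- remove_background(cube)
  expect_s3_class(rb$tissue_mask, "binary_mask")
  expect_true(grid_equal(rb$tissue_mask$grid, g))
  # pixel-exact up to boundary ties (interior must match everywhere)
  expect_gt(mean(rb$tissue_mask$values == dm$values), 0.98)

  flat <- hyper_cube(g, wn, withr::with_seed(4, {
    outer(rep(1, 576), spec_t) + matrix(rnorm(576 * length(wn), 0, 0.01), 576)
  }))
  expect_warning(rb2 <- remove_background(flat), "all pixels")
  expect_true(all(rb2$tissue_mask$values))
})

test_that("the preprocessing chain is deterministic and composes stage by stage", {
  ph <- generate_phantom(phantom_spec(seed = 5, ftir_n = 24, msi_n = 8))
  cfg <- ftir_config(epd_iters = 20)
  a <- ftir_preprocess(ph$cube, cfg)
  b <- ftir_preprocess(ph$cube, cfg)
  expect_identical(a$data, b$data)
  expect_identical(a$tissue_mask, b$tissue_mask)

  # skipping EPD equals composing the remaining stages by hand
  no_epd <- ftir_preprocess(ph$cube, cfg, do_epd = FALSE,
                            do_background = FALSE)
  manual <- ph$cube$data
  manual <- manual - ftirguide:::asls_matrix(manual, cfg)
  spacing <- diff(ph$cube$wavenumbers[1:2])
  manual <- t(apply(manual, 1, function(y) {
    signal::sgolayfilt(y, p = cfg$deriv_polyorder, n = cfg$deriv_window, m = 1)
  })) / spacing
  manual <- ftirguide:::snv_matrix(manual)
  attr(manual, "degenerate") <- NULL
  keep <- (ph$cube$wavenumbers <= 3100 & ph$cube$wavenumbers >= 2900) |
    (ph$cube$wavenumbers <= 1800 & ph$cube$wavenumbers >= 950)
  expect_equal(no_epd$data, manual[, keep], tolerance = 1e-12)

  # retained channel count equals the window channel count
  expect_equal(length(a$wavenumbers), sum(keep))
})

test_that("spectral stages are invariant to pixel storage order", {
  cfg <- ftir_config()
  withr::with_seed(8, {
    Y <- matrix(rnorm(40 * 60, sd = 0.2) + 1, 40, 60)
    perm <- sample(40)
  })
  base <- Y - ftirguide:::asls_matrix(Y, cfg)
  base <- ftirguide:::snv_matrix(base)
  permed <- Y[perm, ] - ftirguide:::asls_matrix(Y[perm, ], cfg)
  permed <- ftirguide:::snv_matrix(permed)
  expect_equal(permed, base[perm, ], tolerance = 1e-12,
               ignore_attr = TRUE)
})
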