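# shared fixture builders (everything generated in code, nothing on disk)

# small random continuous-mode MSI dataset
random_msi <- function(n_rows = 2, n_cols = 2, n_mz = 5, seed = 1,
                       pixel_size = 75, drop_pixels = integer(0)) {
  withr::with_seed(seed, {
    grid <- pixel_grid(n_rows, n_cols, pixel_size)
    idx <- setdiff(seq_len(n_rows * n_cols) - 1L, drop_pixels)
    mz <- sort(runif(n_mz, 400, 900))
    ints <- matrix(rexp(length(idx) * n_mz), length(idx), n_mz)
    msi_dataset(grid, idx, mode = "continuous", mz_axis = mz,
                intensities = ints)
  })
}

# random processed-mode dataset with per-pixel centroid lists
random_msi_processed <- function(n_rows = 2, n_cols = 2, seed = 1) {
  withr::with_seed(seed, {
    grid <- pixel_grid(n_rows, n_cols, 50)
    idx <- seq_len(n_rows * n_cols) - 1L
    pk <- lapply(idx, function(i) {
      n <- sample(1:4, 1)
      data.frame(mz = sort(runif(n, 400, 900)), intensity = rexp(n))
    })
    msi_dataset(grid, idx, mode = "processed", peaks = pk)
  })
}

random_mask <- function(n = 16, seed = 1, p = 0.4, pixel_size = 1) {
  withr::with_seed(seed, {
    binary_mask(pixel_grid(n, n, pixel_size),
                matrix(runif(n * n) < p, n, n))
  })
}

# disk mask for shape tests
disk_mask <- function(n = 32, radius_frac = 0.3, pixel_size = 25) {
  g <- pixel_grid(n, n, pixel_size)
  ctr <- grid_centers(g)
  cx <- (n - 1) / 2 * pixel_size
  on <- (ctr$x - cx)^2 + (ctr$y - cx)^2 <= (radius_frac * n * pixel_size)^2
  binary_mask(g, matrix(on, n, n, byrow = TRUE))
}

# tiny two-class FTIR cube: left half class A, right half class B
two_class_cube <- function(n = 8, n_ch = 20, sep = 1, noise = 0.01,
                           seed = 1, section_id = "s1") {
  withr::with_seed(seed, {
    wn <- seq(1800, 1000, length.out = n_ch)
    a <- exp(-(wn - 1600)^2 / (2 * 40^2))
    b <- exp(-(wn - 1200)^2 / (2 * 40^2))
    g <- pixel_grid(n, n, 25)
    ctr <- grid_centers(g)
    cls <- ifelse(ctr$col < n / 2, 1L, 2L)
    data <- rbind(a, b)[cls, ] * sep +
      matrix(rnorm(n * n * n_ch, sd = noise), n * n, n_ch)
    list(cube = hyper_cube(g, wn, data, section_id = section_id),
         labels = cls)
  })
}
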