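#' FTIR preprocessing configuration
#'
#' Parameters of the FTIR spectral/spatial preprocessing chain, applied in
#' the order: AsLS baseline correction, Savitzky-Golay first derivative,
#' standard normal variate scaling, spectral window selection, edge-preserving
#' (total-variation) denoising, background-pixel removal.
#'
#' @param asls_lambda Smoothness weight of the AsLS baseline (default 1e5).
#' @param asls_p Asymmetry weight in (0, 1); small values let the baseline
#'   hug the spectrum from below (default 0.001).
#' @param asls_iters Maximum AsLS reweighting iterations (default 10).
#' @param deriv_window Savitzky-Golay window length, odd (default 9).
#' @param deriv_polyorder Savitzky-Golay polynomial order (default 2).
#' @param windows List of `(hi, lo)` wavenumber intervals in cm^-1 to retain,
#'   inclusive. Defaults to the lipid (3100-2900) and fingerprint (1800-950)
#'   regions.
#' @param epd_weight Total-variation regularization strength; 0 disables
#'   denoising (default 0.1).
#' @param epd_iters Maximum denoising iterations (default 100).
#' @param bg_min_ratio Minimum foreground/background mean-signal ratio for
#'   the background call; below it, the cube is treated as all-tissue with a
#'   warning (default 1.5).
#' @param seed RNG seed for the background k-means (default 1).
#' @return A list of class `ftir_config`.
#' @export
ftir_config <- function(asls_lambda = 1e5, asls_p = 0.001, asls_iters = 10,
                        deriv_window = 9, deriv_polyorder = 2,
                        windows = list(c(3100, 2900), c(1800, 950)),
                        epd_weight = 0.1, epd_iters = 100,
                        bg_min_ratio = 1.5, seed = 1L) {
  stopifnot(
    asls_p > 0, asls_p < 1, asls_lambda > 0, asls_iters >= 1,
    deriv_window %% 2 == 1, deriv_window > deriv_polyorder,
    epd_weight >= 0, epd_iters >= 1, bg_min_ratio >= 1
  )
  for (w in windows) stopifnot(length(w) == 2)
  structure(
    list(
      asls_lambda = asls_lambda, asls_p = asls_p, asls_iters = asls_iters,
      deriv_window = as.integer(deriv_window),
      deriv_polyorder = as.integer(deriv_polyorder),
      windows = lapply(windows, function(w) sort(as.numeric(w),
                                                 decreasing = TRUE)),
      epd_weight = epd_weight, epd_iters = as.integer(epd_iters),
      bg_min_ratio = bg_min_ratio, seed = as.integer(seed)
    ),
    class = "ftir_config"
  )
}

#' Asymmetric least squares baseline
#'
#' Estimates the baseline `z` of a spectrum `y` as the minimizer of
#' `sum_i w_i (y_i - z_i)^2 + lambda * sum_i (d2 z_i)^2` with asymmetric
#' weights `w_i = p` where `y_i > z_i` and `1 - p` otherwise, iterated until
#' the weights stop changing. With a small `p` the baseline drapes under the
#' peaks. Any affine spectrum is reproduced exactly (second differences of a
#' line vanish).
#'
#' @param y Numeric spectrum (length >= 4, finite).
#' @param cfg An [ftir_config()] (or anything with `asls_lambda`, `asls_p`,
#'   `asls_iters`).
#' @return A list with `baseline` and `corrected` (`y - baseline`).
#' @export
asls_baseline <- function(y, cfg = ftir_config()) {
  y <- as.numeric(y)
  if (length(y) < 4) stop("spectrum too short for AsLS (need >= 4 points)")
  if (any(!is.finite(y))) stop("spectrum must be finite")
  z <- asls_matrix(matrix(y, nrow = 1), cfg)[1, ]
  list(baseline = z, corrected = y - z)
}

# AsLS over the rows of Y; the pentadiagonal penalized system is solved in
# compiled code (banded LDL^T), one factorization per reweighting step
asls_matrix <- function(Y, cfg) {
  if (any(!is.finite(Y))) stop("spectra must be finite for AsLS")
  .asls_baselines(Y, cfg$asls_lambda, cfg$asls_p, cfg$asls_iters)
}

#' Savitzky-Golay first derivative of a spectrum
#'
#' Polynomial-filter first derivative with respect to wavenumber: the
#' per-channel derivative from [signal::sgolayfilt()] divided by the channel
#' spacing, whose sign follows the descending FTIR axis. Exact on polynomials
#' up to `deriv_polyorder` at interior points.
#'
#' @param y Numeric spectrum.
#' @param wavenumbers The spectrum's wavenumber axis (equally spaced).
#' @param cfg An [ftir_config()].
#' @return Derivative series, units of absorbance per cm^-1.
#' @export
first_derivative <- function(y, wavenumbers, cfg = ftir_config()) {
  spacing <- (wavenumbers[length(wavenumbers)] - wavenumbers[1]) /
    (length(wavenumbers) - 1)
  d <- signal::sgolayfilt(as.numeric(y), p = cfg$deriv_polyorder,
                          n = cfg$deriv_window, m = 1)
  d / spacing
}

#' Standard normal variate scaling
#'
#' Centers and scales each spectrum to zero mean and unit (sample, n-1)
#' standard deviation. Invariant under positive affine transforms of the
#' input.
#'
#' @param y Numeric spectrum with positive standard deviation.
#' @return The scaled spectrum.
#' @export
snv <- function(y) {
  s <- stats::sd(y)
  if (!is.finite(s) || s == 0) stop("zero-variance spectrum cannot be SNV-scaled")
  (y - mean(y)) / s
}

# row-wise SNV over a matrix; zero-variance rows are reported, not scaled
snv_matrix <- function(Y) {
  mu <- rowMeans(Y)
  s <- sqrt(rowSums((Y - mu)^2) / (ncol(Y) - 1))
  bad <- !is.finite(s) | s == 0
  s[bad] <- 1
  out <- (Y - mu) / s
  attr(out, "degenerate") <- bad
  out
}

#' Restrict a cube to configured wavenumber windows
#'
#' Keeps exactly the channels whose wavenumber lies inside any configured
#' `(hi, lo)` interval (inclusive), preserving the descending channel order.
#'
#' @param cube A [hyper_cube()].
#' @param cfg An [ftir_config()].
#' @return The restricted [hyper_cube()].
#' @export
select_windows <- function(cube, cfg = ftir_config()) {
  wn <- cube$wavenumbers
  keep <- rep(FALSE, length(wn))
  for (w in cfg$windows) keep <- keep | (wn <= w[1] & wn >= w[2])
  if (!any(keep)) stop("no channels fall inside the configured windows")
  hyper_cube(cube$grid, wn[keep], cube$data[, keep, drop = FALSE],
             tissue_mask = cube$tissue_mask, section_id = cube$section_id)
}

#' Edge-preserving (total-variation) denoising of channel images
#'
#' Applies 2-D Rudin-Osher-Fatemi denoising channel by channel using
#' Chambolle's dual projection algorithm: each channel image `u` minimizes
#' `0.5 * ||u - f||^2 + weight * TV(u)`. Off-tissue pixels are excluded: they
#' are filled with the on-tissue channel mean before denoising (so they do not
#' bleed across the tissue boundary) and restored unchanged afterwards.
#'
#' @param cube A [hyper_cube()].
#' @param cfg An [ftir_config()]; `epd_weight = 0` returns the cube unchanged.
#' @return The denoised [hyper_cube()].
#' @export
epd_denoise <- function(cube, cfg = ftir_config()) {
  if (cfg$epd_weight == 0) return(cube)
  nr <- cube$grid$n_rows
  nc <- cube$grid$n_cols
  mask <- if (is.null(cube$tissue_mask)) NULL else
    matrix(cube$tissue_mask, nr, nc, byrow = TRUE)
  data <- cube$data
  for (ch in seq_len(ncol(data))) {
    img <- matrix(data[, ch], nr, nc, byrow = TRUE)
    if (!is.null(mask)) {
      fill <- mean(img[mask])
      orig <- img
      img[!mask] <- fill
    }
    den <- tv_chambolle(img, cfg$epd_weight, cfg$epd_iters)
    if (!is.null(mask)) {
      out <- orig
      out[mask] <- den[mask]
      den <- out
    }
    data[, ch] <- as.numeric(t(den))
  }
  hyper_cube(cube$grid, cube$wavenumbers, data,
             tissue_mask = cube$tissue_mask, section_id = cube$section_id)
}

# Chambolle (2004) dual projection for min 0.5||u-f||^2 + w TV(u)
tv_chambolle <- function(f, weight, iters, tol = 2e-4) {
  nr <- nrow(f); nc <- ncol(f)
  px <- matrix(0, nr, nc) # forward difference along rows (y)
  py <- matrix(0, nr, nc) # forward difference along cols (x)
  tau <- 0.25
  d <- matrix(0, nr, nc)
  e_prev <- Inf
  for (it in seq_len(iters)) {
    if (it > 1) {
      # divergence of (px, py)
      div <- px - rbind(0, px[-nr, , drop = FALSE])
      div[nr, ] <- -px[nr - 1, ]
      div[1, ] <- px[1, ]
      dvy <- py - cbind(0, py[, -nc, drop = FALSE])
      dvy[, nc] <- -py[, nc - 1]
      dvy[, 1] <- py[, 1]
      d <- -(div + dvy)
    }
    u <- f + d
    gx <- rbind(u[-1, , drop = FALSE] - u[-nr, , drop = FALSE], 0)
    gy <- cbind(u[, -1, drop = FALSE] - u[, -nc, drop = FALSE], 0)
    nrm <- sqrt(gx^2 + gy^2)
    e <- sum(d^2) + weight * sum(nrm)
    scale <- 1 + nrm * (tau / weight)
    px <- (px - tau * gx) / scale
    py <- (py - tau * gy) / scale
    if (is.finite(e_prev) && abs(e_prev - e) < tol * abs(e)) break
    e_prev <- e
  }
  f + d
}

#' Remove tissue-free background pixels
#'
#' Splits the cube's spectra into two groups by k = 2 k-means++ clustering
#' and labels the group with the smaller mean total absolute signal as
#' background (slide surface). If the two groups' mean signals differ by less
#' than `bg_min_ratio`, the cube is assumed all-tissue and kept whole with a
#' warning. An exact tie is broken toward the cluster touching the image
#' border.
#'
#' @param cube A [hyper_cube()].
#' @param cfg An [ftir_config()].
#' @param raw_signal Optional per-pixel total absolute signal from the
#'   *unprocessed* cube, used to decide which cluster is background. After
#'   SNV every spectrum has unit variance, so amplitude information must
#'   come from before scaling; [ftir_preprocess()] passes it automatically.
#' @return The cube with `tissue_mask` set, plus the mask itself in the
#'   `tissue_mask` field of the returned list `(cube, tissue_mask)`.
#' @export
remove_background <- function(cube, cfg = ftir_config(), raw_signal = NULL) {
  nr <- cube$grid$n_rows; nc <- cube$grid$n_cols
  km <- kmeanspp_fit(cube$data, k = 2, seed = cfg$seed, n_init = 3,
                     max_iter = 100)
  sig <- raw_signal %||% rowSums(abs(cube$data))
  m1 <- mean(sig[km$cluster == 1])
  m2 <- mean(sig[km$cluster == 2])
  if (max(m1, m2) < cfg$bg_min_ratio * min(m1, m2)) {
    warning("no clear background/tissue split; keeping all pixels as tissue")
    mask_vec <- rep(TRUE, n_pixels(cube$grid))
  } else if (m1 == m2) {
    lab_img <- matrix(km$cluster, nr, nc, byrow = TRUE)
    border <- c(lab_img[1, ], lab_img[nr, ], lab_img[, 1], lab_img[, nc])
    bg <- as.integer(names(which.max(table(border))))
    mask_vec <- km$cluster != bg
  } else {
    bg <- if (m1 < m2) 1L else 2L
    mask_vec <- km$cluster != bg
  }
  cube2 <- hyper_cube(cube$grid, cube$wavenumbers, cube$data,
                      tissue_mask = mask_vec, section_id = cube$section_id)
  list(
    cube = cube2,
    tissue_mask = binary_mask(cube$grid, matrix(mask_vec, nr, nc, byrow = TRUE))
  )
}

#' Run the full FTIR preprocessing chain
#'
#' AsLS baseline correction, Savitzky-Golay first derivative, SNV scaling,
#' spectral window selection, edge-preserving denoising, and background
#' removal, in that order. Stages can be skipped with the `do_*` switches;
#' skipping a stage is identical to composing the remaining stages by hand.
#' SNV-degenerate (zero-variance) pixels are masked out of the tissue mask
#' rather than erroring, so whole-slide runs survive dead pixels.
#'
#' @param cube A [hyper_cube()].
#' @param cfg An [ftir_config()].
#' @param do_asls,do_deriv,do_snv,do_windows,do_epd,do_background Stage
#'   switches, all TRUE by default.
#' @return The preprocessed [hyper_cube()] with `tissue_mask` set when
#'   background removal ran.
#' @export
ftir_preprocess <- function(cube, cfg = ftir_config(),
                            do_asls = TRUE, do_deriv = TRUE, do_snv = TRUE,
                            do_windows = TRUE, do_epd = TRUE,
                            do_background = TRUE) {
  data <- cube$data
  if (do_asls) data <- data - asls_matrix(data, cfg)
  # baseline-corrected total signal: the amplitude evidence for the later
  # background call (SNV erases amplitudes; raw totals are drift-dominated)
  raw_sig <- rowSums(abs(data))
  if (do_deriv) {
    spacing <- (cube$wavenumbers[length(cube$wavenumbers)] -
                  cube$wavenumbers[1]) / (length(cube$wavenumbers) - 1)
    data <- t(apply(data, 1, function(y) {
      signal::sgolayfilt(y, p = cfg$deriv_polyorder,
                         n = cfg$deriv_window, m = 1)
    })) / spacing
  }
  degenerate <- rep(FALSE, nrow(data))
  if (do_snv) {
    data <- snv_matrix(data)
    degenerate <- attr(data, "degenerate")
    attr(data, "degenerate") <- NULL
  }
  mask0 <- cube$tissue_mask %||% rep(TRUE, nrow(data))
  mask0 <- mask0 & !degenerate
  data[degenerate, ] <- 0
  out <- hyper_cube(cube$grid, cube$wavenumbers, data,
                    tissue_mask = mask0, section_id = cube$section_id)
  if (do_windows) out <- select_windows(out, cfg)
  if (do_epd) out <- epd_denoise(out, cfg)
  if (do_background) {
    rb <- remove_background(out, cfg, raw_signal = raw_sig)
    out <- rb$cube
    out$tissue_mask <- out$tissue_mask & mask0 # keep degenerate pixels out
  }
  out
}
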