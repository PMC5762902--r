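#' Specification of a paired FTIR/MSI phantom
#'
#' Describes a synthetic tissue section imaged by both modalities: a
#' superellipse tissue outline containing a tumor blob and a margin rim
#' (regions partition the tissue; superellipses keep area/perimeter truths
#' computable), per-region FTIR absorbance bands and MALDI peak models, an
#' inter-modality similarity transform, and nuisance parameters. The seed
#' fully determines the generated data.
#'
#' Region labels: 1 = parenchyma, 2 = tumor, 3 = margin rim, 0 = off-tissue.
#'
#' @param ftir_n Side length of the (square) FTIR raster (default 48).
#' @param ftir_pixel_size FTIR pixel pitch in micrometers (default 25).
#' @param msi_n Side length of the MSI raster (default 16).
#' @param msi_pixel_size MSI pixel pitch in micrometers (default 75).
#' @param wn_axis FTIR wavenumber axis in cm^-1 (descending).
#' @param ftir_noise_sd Gaussian absorbance noise (default 0.03, one tenth of the
#'   smallest peak-scale separation between region templates).
#' @param mz_axis MSI profile m/z axis (default 400-900 Da at 0.1 Da).
#' @param msi_noise_sd Gaussian intensity noise of the MSI profiles
#'   (default 1; peak amplitudes are expressed in these units).
#' @param msi_cv Per-pixel, per-peak log-normal coefficient of variation of
#'   peak amplitudes — the matrix/ionization variability that TIC
#'   normalization cannot remove (default 0.3).
#' @param marker_fold Fold-change of each region marker inside its region
#'   relative to everywhere else (default 3).
#' @param truth_transform [similarity_transform()] mapping FTIR physical
#'   coordinates into the MSI frame (default: 30 um right, -20 um up,
#'   3 degrees, scale 1).
#' @param seed RNG seed (default 1).
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(ftir_n = 48, ftir_pixel_size = 25,
                         msi_n = 16, msi_pixel_size = 75,
                         wn_axis = seq(3100, 950, by = -8),
                         ftir_noise_sd = 0.03,
                         mz_axis = seq(400, 900, by = 0.1),
                         msi_noise_sd = 1, msi_cv = 0.3, marker_fold = 3,
                         truth_transform = similarity_transform(30, -20, 3, 1),
                         seed = 1L) {
  structure(
    list(ftir_n = as.integer(ftir_n), ftir_pixel_size = ftir_pixel_size,
         msi_n = as.integer(msi_n), msi_pixel_size = msi_pixel_size,
         wn_axis = wn_axis, ftir_noise_sd = ftir_noise_sd,
         mz_axis = mz_axis, msi_noise_sd = msi_noise_sd, msi_cv = msi_cv,
         marker_fold = marker_fold, truth_transform = truth_transform,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# region label at physical points in the FTIR frame:
# 0 off-tissue, 1 parenchyma, 2 tumor, 3 margin rim
phantom_region_label <- function(spec, x, y) {
  W <- spec$ftir_n * spec$ftir_pixel_size
  cx <- W * 0.5; cy <- W * 0.5
  inside <- function(x, y, x0, y0, a, b, p) {
    (abs((x - x0) / a))^p + (abs((y - y0) / b))^p <= 1
  }
  tissue <- inside(x, y, cx, cy, 0.42 * W, 0.38 * W, 2.5)
  tum <- inside(x, y, cx + 0.12 * W, cy - 0.08 * W, 0.13 * W, 0.11 * W, 2)
  rim <- inside(x, y, cx + 0.12 * W, cy - 0.08 * W,
                0.13 * W * 1.45, 0.11 * W * 1.45, 2) & !tum
  lab <- integer(length(x))
  lab[tissue] <- 1L
  lab[tissue & rim] <- 3L
  lab[tissue & tum] <- 2L
  lab
}

# per-region FTIR absorbance templates: Gaussian bands on the axis
phantom_ftir_templates <- function(wn) {
  band <- function(center, width, amp) amp * exp(-(wn - center)^2 / (2 * width^2))
  common <- function(a2925, a2850, a1740, a1650, a1550, a1240, a1080) {
    band(2925, 15, a2925) + band(2850, 12, a2850) + band(1740, 12, a1740) +
      band(1650, 25, a1650) + band(1550, 20, a1550) +
      band(1240, 18, a1240) + band(1080, 20, a1080)
  }
  rbind(
    background = 0.02 * exp(-(wn - 2000)^2 / (2 * 800^2)),
    parenchyma = common(0.40, 0.20, 0.05, 1.00, 0.50, 0.30, 0.35),
    tumor      = common(0.70, 0.35, 0.05, 0.90, 0.45, 0.45, 0.60),
    margin     = common(0.55, 0.28, 0.40, 0.95, 0.48, 0.35, 0.45)
  )
}

# MSI peak model: shared lipid peaks plus one marker per region; amplitudes
# in units of the profile noise SD, rows = regions 0..3
phantom_msi_peaks <- function(marker_fold = 3) {
  lo <- 60 / marker_fold
  tibble::tibble(
    mz = c(496.3, 760.6, 798.5, 834.5, 885.5),
    role = c("shared", "shared", "marker_tumor", "marker_margin",
             "marker_parenchyma"),
    amp_background = c(0, 0, 0, 0, 0),
    amp_parenchyma = c(60, 80, lo, lo, 60),
    amp_tumor = c(60, 80, 60, lo, lo),
    amp_margin = c(60, 80, lo, 60, lo)
  )
}

#' Generate a paired FTIR/MSI phantom
#'
#' Builds the FTIR cube (region band templates + per-pixel affine baseline
#' drift + Gaussian noise), the MSI profile dataset (per-region peaks with
#' log-normal per-pixel amplitude variation, two-isotopologue clusters at
#' +1.0034 Da with an M+1 ratio from a simple carbon-count model, smooth
#' baseline + Gaussian noise), ground-truth label maps on both grids, and
#' the true inter-modality transform. The same seed reproduces the output
#' bit for bit.
#'
#' @param spec A [phantom_spec()].
#' @param section_id Label stamped on the generated objects.
#' @return A list: `cube` ([hyper_cube()]), `msi` ([msi_dataset()],
#'   continuous profile mode), `truth_ftir` and `truth_msi`
#'   ([segment_map()]s, k = 3), `truth_transform`, and a `manifest` list
#'   recording the planted markers (`mz`, `region`, `fold`), region pixel
#'   counts and the seed.
#' @export
generate_phantom <- function(spec = phantom_spec(), section_id = "phantom") {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  fg <- pixel_grid(spec$ftir_n, spec$ftir_n, spec$ftir_pixel_size)
  mg <- pixel_grid(spec$msi_n, spec$msi_n, spec$msi_pixel_size)

  fc <- grid_centers(fg)
  lab_f <- phantom_region_label(spec, fc$x, fc$y)

  # MSI pixel centers pulled back into the FTIR frame through the truth
  inv <- invert_transform(spec$truth_transform)
  mc <- grid_centers(mg)
  src <- apply_transform(inv, cbind(mc$x, mc$y))
  lab_m <- phantom_region_label(spec, src[, 1], src[, 2])

  # --- FTIR cube ---
  wn <- spec$wn_axis
  tmpl <- phantom_ftir_templates(wn)
  npx <- nrow(fc); nch <- length(wn)
  data <- tmpl[lab_f + 1L, , drop = FALSE]
  # per-pixel affine drift (removed exactly by the AsLS baseline)
  b0 <- stats::runif(npx, 0.05, 0.25)
  b1 <- stats::runif(npx, -0.05, 0.05)
  drift <- outer(b0, rep(1, nch)) + outer(b1, (wn - 2000) / 1000)
  noise <- matrix(stats::rnorm(npx * nch, sd = spec$ftir_noise_sd), npx, nch)
  cube <- hyper_cube(fg, wn, data + drift + noise, section_id = section_id)

  # --- MSI profile dataset ---
  mz <- spec$mz_axis
  pk <- phantom_msi_peaks(spec$marker_fold)
  amp_cols <- c("amp_background", "amp_parenchyma", "amp_tumor", "amp_margin")
  nmz <- length(mz)
  nmp <- nrow(mc)
  sig <- spec$msi_noise_sd
  baseline <- 10 * sig * exp(-(mz - mz[1]) / 250) + 3 * sig
  ints <- matrix(stats::rnorm(nmp * nmz, sd = sig), nmp, nmz)
  ints <- sweep(ints, 2, baseline, "+")
  sd_log <- sqrt(log(1 + spec$msi_cv^2))
  peak_shape <- function(center, apex) {
    lo <- max(1L, findInterval(center - 1, mz))
    hi <- min(nmz, findInterval(center + 1, mz) + 1L)
    idx <- lo:hi
    list(idx = idx, y = apex * exp(-(mz[idx] - center)^2 / (2 * 0.12^2)))
  }
  for (p in seq_len(nrow(pk))) {
    n_c <- round(pk$mz[p] / 14) # crude carbon count from the lipid mass
    iso_ratio <- min(0.011 * n_c, 0.9)
    for (px in seq_len(nmp)) {
      base_amp <- pk[[amp_cols[lab_m[px] + 1L]]][p]
      if (base_amp <= 0) next
      amp <- base_amp * stats::rlnorm(1, -sd_log^2 / 2, sd_log)
      m0 <- peak_shape(pk$mz[p], amp)
      ints[px, m0$idx] <- ints[px, m0$idx] + m0$y
      m1 <- peak_shape(pk$mz[p] + 1.0034, amp * iso_ratio)
      ints[px, m1$idx] <- ints[px, m1$idx] + m1$y
    }
  }
  ints[ints < 0] <- 0
  msi <- msi_dataset(mg, mc$pixel, mode = "continuous", mz_axis = mz,
                     intensities = ints, section_id = section_id)

  truth_ftir <- segment_map(fg, matrix(lab_f, fg$n_rows, fg$n_cols,
                                       byrow = TRUE), 3L,
                            section_id = section_id)
  truth_msi <- segment_map(mg, matrix(lab_m, mg$n_rows, mg$n_cols,
                                      byrow = TRUE), 3L,
                           section_id = section_id)
  manifest <- list(
    seed = spec$seed,
    markers = data.frame(
      mz = pk$mz[grepl("marker", pk$role)],
      region = c(2L, 3L, 1L),
      fold = spec$marker_fold
    ),
    region_px_ftir = as.integer(table(factor(lab_f, levels = 0:3))),
    region_px_msi = as.integer(table(factor(lab_m, levels = 0:3))),
    truth_transform = unclass(spec$truth_transform)
  )
  list(cube = cube, msi = msi, truth_ftir = truth_ftir, truth_msi = truth_msi,
       truth_transform = spec$truth_transform, manifest = manifest)
}

#' Degrade an MSI dataset with acquisition nuisance effects
#'
#' Applies a smooth multiplicative ion-suppression field (a Gaussian dip of
#' the given `depth` centered at `center_frac` of the image extent) and
#' per-pixel multiplicative log-normal speckle (matrix inhomogeneity).
#' Intensities stay non-negative; zero-strength nuisance is an exact
#' identity. Both effects scale whole pixel spectra, so TIC normalization
#' removes them.
#'
#' @param ds A continuous-mode [msi_dataset()].
#' @param suppression_depth Depth of the suppression dip in `[0, 1)`
#'   (default 0.5; 0 disables).
#' @param suppression_width Width of the dip as a fraction of the image
#'   extent (default 0.35).
#' @param center_frac `(x, y)` center of the dip as fractions of the extent.
#' @param speckle_sd Log-scale SD of the per-pixel speckle (default 0.2;
#'   0 disables).
#' @param seed RNG seed.
#' @return The degraded [msi_dataset()].
#' @export
degrade_msi <- function(ds, suppression_depth = 0.5, suppression_width = 0.35,
                        center_frac = c(0.4, 0.6), speckle_sd = 0.2,
                        seed = 1L) {
  stopifnot(inherits(ds, "msi_dataset"), ds$mode == "continuous",
            suppression_depth >= 0, suppression_depth < 1, speckle_sd >= 0)
  if (suppression_depth == 0 && speckle_sd == 0) return(ds)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  g <- ds$grid
  ctr <- grid_centers(g)
  px <- ctr[match(ds$pixel_idx, ctr$pixel), ]
  W <- g$n_cols * g$pixel_size; H <- g$n_rows * g$pixel_size
  cx <- g$origin[1] + center_frac[1] * W
  cy <- g$origin[2] + center_frac[2] * H
  w <- suppression_width * max(W, H)
  field <- 1 - suppression_depth *
    exp(-((px$x - cx)^2 + (px$y - cy)^2) / (2 * w^2))
  speckle <- if (speckle_sd > 0) {
    stats::rlnorm(length(field), -speckle_sd^2 / 2, speckle_sd)
  } else rep(1, length(field))
  fac <- field * speckle
  msi_dataset(g, ds$pixel_idx, mode = "continuous", mz_axis = ds$mz_axis,
              intensities = ds$intensities * fac, polarity = ds$polarity,
              section_id = ds$section_id)
}

#' Random superellipse tissue mask
#'
#' A seeded superellipse tissue outline on its own grid, with mild random
#' variation of the radii, exponent and center — the stand-in tissue shape
#' used by the registration experiments.
#'
#' @param n Side length in pixels (default 256).
#' @param pixel_size Pixel pitch in micrometers (default 25).
#' @param seed RNG seed.
#' @return A [binary_mask()].
#' @export
phantom_tissue_mask <- function(n = 256, pixel_size = 25, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  g <- pixel_grid(n, n, pixel_size)
  W <- n * pixel_size
  a <- stats::runif(1, 0.32, 0.42) * W
  b <- stats::runif(1, 0.28, 0.40) * W
  p <- stats::runif(1, 2, 3)
  cx <- W * stats::runif(1, 0.45, 0.55)
  cy <- W * stats::runif(1, 0.45, 0.55)
  ctr <- grid_centers(g)
  on <- (abs((ctr$x - cx) / a))^p + (abs((ctr$y - cy) / b))^p <= 1
  binary_mask(g, matrix(on, n, n, byrow = TRUE))
}

#' Perturb a mask by a known transform plus boundary noise
#'
#' Warps the mask through `t` onto its own grid and randomly flips pixels in
#' the one-pixel boundary ring with probability `flip_prob` — the seeded
#' degradation used to exercise the registration recovery envelope.
#'
#' @param mask A [binary_mask()].
#' @param t A [similarity_transform()].
#' @param flip_prob Flip probability on the boundary ring (default 0.3).
#' @param seed RNG seed.
#' @return The perturbed [binary_mask()].
#' @export
perturb_mask <- function(mask, t, flip_prob = 0.3, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  warped <- warp_mask(mask, t, mask$grid)
  v <- warped$values
  nr <- nrow(v); nc <- ncol(v)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- v
  nb_same <- pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  nb_any <- pad[1:nr, 2:(nc + 1)] | pad[3:(nr + 2), 2:(nc + 1)] |
    pad[2:(nr + 1), 1:nc] | pad[2:(nr + 1), 3:(nc + 2)]
  boundary <- (v & !nb_same) | (!v & nb_any)
  flip <- boundary & matrix(stats::runif(nr * nc) < flip_prob, nr, nc)
  binary_mask(mask$grid, xor(v, flip))
}
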