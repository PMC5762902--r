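#' One seeded registration-recovery trial
#'
#' Draws a superellipse tissue mask, perturbs it by a similarity transform
#' plus boundary noise, registers the perturbed mask back onto the original,
#' and reports the post-registration Dice coefficient. With `NULL`
#' perturbation arguments the perturbation is drawn uniformly from the
#' documented recovery envelope (translation up to 15% of the extent,
#' rotation up to 15 degrees, scale within 10%).
#'
#' @param seed Trial seed; fixes the mask shape, the perturbation draw and
#'   the boundary noise.
#' @param n Mask side length in pixels (default 256).
#' @param translation_frac Translation as a fraction of the physical extent
#'   (magnitude; direction is seeded), or NULL to draw in `[0, 0.15]`.
#' @param theta Rotation in degrees, or NULL to draw in `[-15, 15]`.
#' @param scale Scale factor, or NULL to draw in `[0.9, 1.1]`.
#' @param flip_prob Boundary-noise flip probability (default 0.3).
#' @return A one-row tibble: `seed`, `dsc`, `converged`, the perturbation
#'   actually applied (`translation_frac`, `theta`, `scale`) and the
#'   recovered transform parameters.
#' @export
registration_trial <- function(seed, n = 256, translation_frac = NULL,
                               theta = NULL, scale = NULL, flip_prob = 0.3) {
  mask <- phantom_tissue_mask(n, 25, seed = seed)
  ext <- n * mask$grid$pixel_size
  draws <- withr_seed_draws(seed, 4)
  if (is.null(translation_frac)) translation_frac <- 0.15 * draws[1]
  if (is.null(theta)) theta <- 15 * (2 * draws[2] - 1)
  if (is.null(scale)) scale <- 0.9 + 0.2 * draws[3]
  ang <- 2 * pi * draws[4]
  tr <- similarity_transform(
    translation_frac * ext * cos(ang), translation_frac * ext * sin(ang),
    theta, scale, center = c(ext / 2, ext / 2)
  )
  pert <- perturb_mask(mask, tr, flip_prob = flip_prob, seed = seed)
  res <- register(pert, mask)
  tibble::tibble(
    seed = seed, dsc = res$dsc, converged = res$converged,
    translation_frac = translation_frac, theta = theta, scale = scale,
    tx = res$transform$tx, ty = res$transform$ty,
    theta_hat = res$transform$theta, s_hat = res$transform$s
  )
}

# uniform(0,1) draws without disturbing the caller's RNG stream
withr_seed_draws <- function(seed, k) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed + 17)
  stats::runif(k)
}

#' One seeded FTIR-versus-MSI segmentation robustness trial
#'
#' Generates a matched phantom pair, segments the FTIR cube (full
#' preprocessing chain + k-means++, k = 3) and the nuisance-degraded MSI
#' dataset (TIC / top-hat / peak picking / binning + k-means++, k = 3), and
#' scores each modality by the best Dice overlap of any segment against the
#' ground-truth tumor region on that modality's own grid.
#'
#' @param seed Trial seed.
#' @param spec Optional [phantom_spec()]; its seed is overridden by `seed`.
#' @return A one-row tibble: `seed`, `dice_ftir`, `dice_msi`.
#' @export
modality_robustness_trial <- function(seed, spec = NULL) {
  if (is.null(spec)) spec <- phantom_spec(seed = seed)
  spec$seed <- as.integer(seed)
  ph <- generate_phantom(spec)
  pp <- ftir_preprocess(ph$cube)
  seg_f <- kmeanspp_joint(list(pp), seg_config(3, seed = 1))[[1]]
  d_f <- max(vapply(seq_len(seg_f$k), function(i) {
    dice(segment_mask(seg_f, i), segment_mask(ph$truth_ftir, 2))
  }, numeric(1)))
  degraded <- degrade_msi(ph$msi, seed = seed)
  binned <- msi_preprocess(degraded)
  seg_m <- spatially_aware_cluster(binned,
                                   seg_config(3, seed = 1, spatial_radius = 0))
  d_m <- max(vapply(seq_len(seg_m$k), function(i) {
    dice(segment_mask(seg_m, i), segment_mask(ph$truth_msi, 2))
  }, numeric(1)))
  tibble::tibble(seed = seed, dice_ftir = d_f, dice_msi = d_m)
}
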