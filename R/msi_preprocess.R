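#' MSI preprocessing configuration
#'
#' Parameters for the MALDI spectral pipeline: TIC normalization, top-hat
#' baseline correction, supersmoother noise estimation, S/N peak picking and
#' peak binning, applied in that order.
#'
#' @param tic_target Total intensity after TIC normalization (default 1).
#' @param tophat_halfwidth Half-width in channels of the flat structuring
#'   element of the morphological opening (default 75, sized for TOF
#'   profiles).
#' @param snr_threshold Signal-to-noise threshold for peak picking
#'   (default 3).
#' @param supersmoother_spans Candidate span fractions of the variable-span
#'   smoother, ascending (default `c(0.05, 0.2, 0.5)`).
#' @param bin_tolerance Maximum bin width for peak binning, in Da
#'   (default 0.1; use `bin_ppm` for resolution-proportional widths).
#' @param bin_ppm If not `NULL`, bin tolerance in ppm of the bin center,
#'   overriding `bin_tolerance` (2 ppm suits FTICR data).
#' @return A list of class `msi_config`.
#' @export
msi_config <- function(tic_target = 1, tophat_halfwidth = 75,
                       snr_threshold = 3,
                       supersmoother_spans = c(0.05, 0.2, 0.5),
                       bin_tolerance = 0.1, bin_ppm = NULL) {
  stopifnot(
    tic_target > 0, tophat_halfwidth >= 1, snr_threshold > 0,
    all(supersmoother_spans > 0), all(supersmoother_spans < 1),
    !is.unsorted(supersmoother_spans), bin_tolerance > 0
  )
  structure(
    list(tic_target = tic_target,
         tophat_halfwidth = as.integer(tophat_halfwidth),
         snr_threshold = snr_threshold,
         supersmoother_spans = supersmoother_spans,
         bin_tolerance = bin_tolerance, bin_ppm = bin_ppm),
    class = "msi_config"
  )
}

#' Total ion current normalization
#'
#' Scales a spectrum so its intensities sum to `tic_target`; relative peak
#' ratios are untouched. A zero-TIC spectrum cannot be scaled and errors;
#' dataset-level wrappers mask such pixels out instead.
#'
#' @param y Non-negative intensity vector with positive total.
#' @param cfg An [msi_config()].
#' @return The scaled spectrum.
#' @export
tic_normalize <- function(y, cfg = msi_config()) {
  s <- sum(y)
  if (!is.finite(s) || s <= 0) stop("zero (or non-finite) TIC; cannot normalize")
  y * (cfg$tic_target / s)
}

#' Top-hat baseline correction
#'
#' The baseline is the morphological opening of the spectrum (erosion then
#' dilation with a flat structuring element of half-width
#' `tophat_halfwidth` channels); the corrected spectrum is the non-negative
#' difference. Opening is idempotent, so correcting twice equals correcting
#' once.
#'
#' @param y Intensity vector.
#' @param cfg An [msi_config()].
#' @return A list with `baseline` and `corrected`.
#' @export
tophat_baseline <- function(y, cfg = msi_config()) {
  h <- cfg$tophat_halfwidth
  op <- .run_max(.run_min(as.numeric(y), h), h)
  list(baseline = op, corrected = y - op)
}

#' Supersmoother noise reference
#'
#' Fits Friedman's variable-span supersmoother (local linear fits at three
#' spans, per-point span selection by cross-validated residual, blended by
#' smoothing the span choice) to intensity versus channel index and returns
#' the smooth curve, used as the noise level for S/N peak picking. Very
#' short spectra fall back to a global linear fit with a warning.
#'
#' @param y Intensity vector.
#' @param cfg An [msi_config()].
#' @return Noise level per channel (same length as `y`).
#' @export
supersmoother_noise <- function(y, cfg = msi_config()) {
  n <- length(y)
  if (n < ceiling(1 / min(cfg$supersmoother_spans)) || n < 10) {
    warning("spectrum too short for the supersmoother; using a linear fit")
    i <- seq_len(n)
    return(stats::fitted(stats::lm(y ~ i)))
  }
  sm <- stats::supsmu(seq_len(n), y)
  # supsmu returns values at (sorted, unique) x = 1..n already
  out <- rep(NA_real_, n)
  out[sm$x] <- sm$y
  if (anyNA(out)) out <- stats::approx(sm$x, sm$y, xout = seq_len(n),
                                       rule = 2)$y
  out
}

#' Pick peaks above a signal-to-noise threshold
#'
#' Local maxima of the (baseline-corrected) spectrum whose intensity reaches
#' `snr_threshold` times the noise reference at that channel. Plateau ties
#' resolve to the leftmost channel. A flat spectrum therefore yields no
#' peaks.
#'
#' @param y Corrected intensity vector.
#' @param mz m/z axis (same length); defaults to channel indices.
#' @param noise Noise level per channel; computed by
#'   [supersmoother_noise()] when missing.
#' @param cfg An [msi_config()].
#' @return A tibble with columns `mz`, `intensity`, `snr`, ordered by m/z.
#' @export
pick_peaks <- function(y, mz = seq_along(y), noise = NULL,
                       cfg = msi_config()) {
  n <- length(y)
  if (is.null(noise)) noise <- supersmoother_noise(y, cfg)
  noise <- pmax(noise, 1e-12)
  is_max <- logical(n)
  if (n >= 3) {
    left <- y[2:(n - 1)] > y[1:(n - 2)]
    right <- y[2:(n - 1)] >= y[3:n]
    # strict rise on the left, non-strict on the right: plateaus resolve to
    # their leftmost channel; flat spectra yield nothing
    is_max[2:(n - 1)] <- left & right
    # drop plateau continuations (equal neighbors already claimed left)
  }
  snr <- y / noise
  hit <- which(is_max & snr >= cfg$snr_threshold)
  tibble::tibble(mz = mz[hit], intensity = y[hit], snr = snr[hit])
}

#' Bin centroids onto a common m/z axis
#'
#' Greedy single-linkage binning of the pooled centroids of all pixels:
#' sorted m/z values are split wherever the gap between neighbors exceeds
#' the tolerance, and any resulting bin wider than the tolerance is split
#' again at its largest internal gap. Each pixel's feature value in a bin is
#' the maximum intensity of its centroids there, 0 if it has none. The
#' result is independent of pixel enumeration order.
#'
#' @param peaks A list of per-pixel peak tibbles (`mz`, `intensity`), e.g.
#'   from [pick_peaks()], or a processed-mode [msi_dataset()].
#' @param cfg An [msi_config()].
#' @param pixel_idx,grid,section_id Passed through to the returned dataset
#'   when `peaks` is a bare list.
#' @return A continuous-mode [msi_dataset()] whose `mz_axis` holds the bin
#'   centers (ascending) and whose matrix holds the binned intensities.
#' @export
bin_peaks <- function(peaks, cfg = msi_config(), pixel_idx = NULL,
                      grid = NULL, section_id = "section") {
  if (inherits(peaks, "msi_dataset")) {
    stopifnot(peaks$mode == "processed")
    grid <- peaks$grid
    pixel_idx <- peaks$pixel_idx
    section_id <- peaks$section_id
    pk <- peaks$peaks
  } else {
    pk <- peaks
    if (is.null(grid)) {
      grid <- pixel_grid(1, length(pk), 1)
      pixel_idx <- seq_along(pk) - 1L
    }
  }
  np <- length(pk)
  all_mz <- unlist(lapply(pk, function(p) p$mz), use.names = FALSE)
  if (length(all_mz) == 0) {
    return(msi_dataset(grid, pixel_idx, mode = "continuous",
                       mz_axis = numeric(0),
                       intensities = matrix(0, np, 0),
                       section_id = section_id))
  }
  u <- sort(unique(all_mz))
  tol_at <- function(mz) {
    if (is.null(cfg$bin_ppm)) cfg$bin_tolerance else mz * cfg$bin_ppm * 1e-6
  }
  bin_id <- assign_bins(u, tol_at)
  centers <- vapply(split(u, bin_id), mean, numeric(1))
  nb <- length(centers)
  # map every centroid of every pixel into its bin; value = max intensity
  lut <- stats::setNames(bin_id, format(u, digits = 15))
  mat <- matrix(0, np, nb)
  for (i in seq_len(np)) {
    p <- pk[[i]]
    if (!nrow(as.data.frame(p))) next
    b <- bin_id[match(p$mz, u)]
    for (j in seq_along(b)) {
      mat[i, b[j]] <- max(mat[i, b[j]], p$intensity[j])
    }
  }
  msi_dataset(grid, pixel_idx, mode = "continuous", mz_axis = unname(centers),
              intensities = mat, section_id = section_id)
}

# split sorted unique m/z values into bins: break at gaps > tol, then
# recursively split any bin wider than tol at its largest gap
assign_bins <- function(u, tol_at) {
  n <- length(u)
  ids <- integer(n)
  nxt <- 0L
  assign_range <- function(lo, hi) {
    tol <- tol_at(mean(u[c(lo, hi)]))
    if (lo == hi || u[hi] - u[lo] <= tol) {
      nxt <<- nxt + 1L
      ids[lo:hi] <<- nxt
      return(invisible())
    }
    gaps <- diff(u[lo:hi])
    big <- which(gaps > tol)
    if (length(big)) {
      splits <- c(lo - 1L, lo - 1L + big, hi)
    } else {
      splits <- c(lo - 1L, lo - 1L + which.max(gaps), hi)
    }
    for (s in seq_len(length(splits) - 1L)) {
      assign_range(splits[s] + 1L, splits[s + 1L])
    }
  }
  assign_range(1L, n)
  ids
}

#' Run the MSI spectral pipeline on a dataset
#'
#' TIC normalization, top-hat baseline correction, supersmoother noise
#' estimation and S/N peak picking for every populated pixel of a
#' continuous-mode dataset, followed by [bin_peaks()] onto a common axis.
#' Zero-TIC pixels are dropped with a warning rather than zero-filled.
#'
#' @param ds A continuous-mode (profile) [msi_dataset()].
#' @param cfg An [msi_config()].
#' @return A continuous-mode binned [msi_dataset()] (bin centers as axis).
#' @export
msi_preprocess <- function(ds, cfg = msi_config()) {
  stopifnot(inherits(ds, "msi_dataset"), ds$mode == "continuous")
  tic <- rowSums(ds$intensities)
  keep <- tic > 0
  if (!all(keep)) {
    warning(sprintf("dropping %d zero-TIC pixel(s)", sum(!keep)))
  }
  idx <- ds$pixel_idx[keep]
  pk <- vector("list", sum(keep))
  r <- 0L
  for (i in which(keep)) {
    r <- r + 1L
    y <- tic_normalize(ds$intensities[i, ], cfg)
    th <- tophat_baseline(y, cfg)
    pk[[r]] <- pick_peaks(th$corrected, mz = ds$mz_axis, cfg = cfg)
  }
  bin_peaks(pk, cfg, pixel_idx = idx, grid = ds$grid,
            section_id = ds$section_id)
}
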