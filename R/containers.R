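#' FTIR hyperspectral cube
#'
#' Absorbance spectra on a physical pixel grid. Spectra are stored as a
#' pixel-by-channel matrix in row-major pixel order (pixel `(r, c)` is row
#' `r * n_cols + c + 1`). The wavenumber axis is stored strictly descending,
#' the FTIR convention; constructors reverse an ascending axis.
#'
#' @param grid A [pixel_grid()].
#' @param wavenumbers Wavenumber axis in cm^-1, strictly monotonic, length >= 2.
#' @param data Numeric matrix, `n_pixels x length(wavenumbers)`.
#' @param tissue_mask Optional logical vector of length `n_pixels` (TRUE =
#'   tissue); NULL means all pixels are considered valid.
#' @param section_id Character label for the tissue section.
#' @return An object of class `hyper_cube`.
#' @export
hyper_cube <- function(grid, wavenumbers, data, tissue_mask = NULL,
                       section_id = "section") {
  stopifnot(inherits(grid, "pixel_grid"))
  wavenumbers <- as.numeric(wavenumbers)
  if (length(wavenumbers) < 2) stop("wavenumber axis must have length >= 2")
  d <- diff(wavenumbers)
  if (all(d > 0)) { # ascending on input: flip to the descending convention
    wavenumbers <- rev(wavenumbers)
    data <- data[, rev(seq_len(ncol(data))), drop = FALSE]
  } else if (!all(d < 0)) {
    stop("wavenumber axis must be strictly monotonic")
  }
  data <- as.matrix(data)
  if (nrow(data) != n_pixels(grid) || ncol(data) != length(wavenumbers)) {
    stop(sprintf(
      "data must be %d pixels x %d channels, got %d x %d",
      n_pixels(grid), length(wavenumbers), nrow(data), ncol(data)
    ))
  }
  if (!is.null(tissue_mask)) {
    stopifnot(is.logical(tissue_mask), length(tissue_mask) == n_pixels(grid))
    if (any(!is.finite(data[tissue_mask, ]))) {
      stop("absorbance must be finite at all tissue pixels")
    }
  } else if (any(!is.finite(data))) {
    stop("absorbance must be finite (or pass a tissue_mask excluding bad pixels)")
  }
  structure(
    list(
      grid = grid, wavenumbers = wavenumbers, data = data,
      tissue_mask = tissue_mask, section_id = as.character(section_id)
    ),
    class = "hyper_cube"
  )
}

#' @export
print.hyper_cube <- function(x, ...) {
  cat(sprintf(
    "<hyper_cube> '%s': %s, %d channels (%.4g..%.4g cm-1)%s\n",
    x$section_id, format(x$grid), length(x$wavenumbers),
    max(x$wavenumbers), min(x$wavenumbers),
    if (is.null(x$tissue_mask)) "" else
      sprintf(", %d/%d tissue px", sum(x$tissue_mask), n_pixels(x$grid))
  ))
  invisible(x)
}

cube_tissue_idx <- function(cube) {
  if (is.null(cube$tissue_mask)) seq_len(n_pixels(cube$grid))
  else which(cube$tissue_mask)
}

#' MALDI mass spectrometry imaging dataset
#'
#' Per-pixel mass spectra on a physical grid. `continuous` mode shares one m/z
#' axis across pixels (intensity matrix, one row per populated pixel);
#' `processed` mode stores per-pixel centroid lists. Pixels absent from the
#' file (holes) are simply not listed in `pixel_idx`: absence is distinct from
#' zero intensity.
#'
#' @param grid A [pixel_grid()].
#' @param pixel_idx 0-based linear (row-major) indices of populated pixels.
#' @param mode `"continuous"` or `"processed"`.
#' @param mz_axis Shared m/z axis (continuous mode), strictly increasing.
#' @param intensities Matrix `length(pixel_idx) x length(mz_axis)`
#'   (continuous mode), non-negative.
#' @param peaks List (one element per populated pixel) of data frames with
#'   columns `mz` (strictly increasing) and `intensity` (processed mode).
#' @param polarity `"positive"` or `"negative"`.
#' @param section_id Character label.
#' @return An object of class `msi_dataset`.
#' @export
msi_dataset <- function(grid, pixel_idx, mode = c("continuous", "processed"),
                        mz_axis = NULL, intensities = NULL, peaks = NULL,
                        polarity = c("positive", "negative"),
                        section_id = "section") {
  mode <- match.arg(mode)
  polarity <- match.arg(polarity)
  stopifnot(inherits(grid, "pixel_grid"))
  pixel_idx <- as.integer(pixel_idx)
  if (any(pixel_idx < 0 | pixel_idx >= n_pixels(grid))) {
    stop("pixel_idx out of grid range")
  }
  if (anyDuplicated(pixel_idx)) stop("duplicate pixel indices")
  if (mode == "continuous") {
    mz_axis <- as.numeric(mz_axis)
    if (length(mz_axis) && any(diff(mz_axis) <= 0)) {
      stop("m/z axis must be strictly increasing")
    }
    intensities <- as.matrix(intensities)
    stopifnot(
      nrow(intensities) == length(pixel_idx),
      ncol(intensities) == length(mz_axis)
    )
    if (any(intensities < 0)) stop("intensities must be >= 0")
    peaks <- NULL
  } else {
    stopifnot(is.list(peaks), length(peaks) == length(pixel_idx))
    for (p in peaks) {
      stopifnot(all(c("mz", "intensity") %in% names(p)))
      if (length(p$mz) > 1 && any(diff(p$mz) <= 0)) {
        stop("per-pixel m/z values must be strictly increasing")
      }
      if (any(p$intensity < 0)) stop("intensities must be >= 0")
    }
    mz_axis <- NULL
    intensities <- NULL
  }
  structure(
    list(
      grid = grid, pixel_idx = pixel_idx, mode = mode, mz_axis = mz_axis,
      intensities = intensities, peaks = peaks, polarity = polarity,
      section_id = as.character(section_id)
    ),
    class = "msi_dataset"
  )
}

#' @export
print.msi_dataset <- function(x, ...) {
  extra <- if (x$mode == "continuous") {
    sprintf("%d m/z channels", length(x$mz_axis))
  } else {
    sprintf("centroided, median %d peaks/px",
            as.integer(stats::median(vapply(x$peaks, function(p) length(p$mz), 1L))))
  }
  cat(sprintf(
    "<msi_dataset> '%s': %s, %d/%d pixels populated, %s mode (%s), %s\n",
    x$section_id, format(x$grid), length(x$pixel_idx), n_pixels(x$grid),
    x$mode, x$polarity, extra
  ))
  invisible(x)
}

#' Binary mask on a pixel grid
#'
#' @param grid A [pixel_grid()].
#' @param values Logical matrix `n_rows x n_cols` (TRUE = foreground).
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(grid, values) {
  stopifnot(inherits(grid, "pixel_grid"))
  values <- as.matrix(values)
  storage.mode(values) <- "logical"
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols) {
    stop("mask shape must match grid")
  }
  if (any(is.na(values))) stop("mask must not contain NA")
  structure(list(grid = grid, values = values), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf(
    "<binary_mask> %s, %d/%d on\n",
    format(x$grid), sum(x$values), length(x$values)
  ))
  invisible(x)
}

mask_area_px <- function(mask) sum(mask$values)

#' Segment label map
#'
#' Integer cluster index (IDX) per pixel; 0 is reserved for background /
#' off-tissue pixels. Jointly clustered sections share the same IDX meaning.
#'
#' @param grid A [pixel_grid()].
#' @param labels Integer matrix `n_rows x n_cols` with values in `0..k`.
#' @param k Number of segments.
#' @param section_id Character label.
#' @return An object of class `segment_map`.
#' @export
segment_map <- function(grid, labels, k, section_id = "section") {
  stopifnot(inherits(grid, "pixel_grid"))
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (nrow(labels) != grid$n_rows || ncol(labels) != grid$n_cols) {
    stop("label image shape must match grid")
  }
  k <- as.integer(k)
  if (any(labels < 0L | labels > k)) stop("labels must lie in 0..k")
  structure(
    list(grid = grid, labels = labels, k = k,
         section_id = as.character(section_id)),
    class = "segment_map"
  )
}

#' @export
print.segment_map <- function(x, ...) {
  tab <- table(factor(x$labels[x$labels > 0], levels = seq_len(x$k)))
  cat(sprintf(
    "<segment_map> '%s': %s, k = %d (sizes: %s), %d background px\n",
    x$section_id, format(x$grid), x$k,
    paste(as.integer(tab), collapse = ", "), sum(x$labels == 0L)
  ))
  invisible(x)
}

#' Binary mask of one segment
#'
#' @param seg A [segment_map()].
#' @param idx Segment index (IDX) to extract.
#' @return A [binary_mask()] that is TRUE where `labels == idx`.
#' @export
segment_mask <- function(seg, idx) {
  stopifnot(inherits(seg, "segment_map"), idx >= 1, idx <= seg$k)
  binary_mask(seg$grid, seg$labels == as.integer(idx))
}

#' Construct a ranked feature table
#'
#' A tibble of segment-discriminating m/z features ordered by a criterion
#' score, as produced by [rank_features()].
#'
#' @param mz m/z values in Da.
#' @param criterion Non-negative criterion scores, descending.
#' @param direction `"up"` or `"down"`: sign of the in-segment mean shift.
#' @param segment_id Segment index the table belongs to.
#' @return A tibble of class `ranked_features` with columns
#'   `mz, criterion, direction, rank, segment_id`.
#' @export
ranked_features <- function(mz, criterion, direction, segment_id) {
  stopifnot(
    length(mz) == length(criterion), length(mz) == length(direction),
    all(criterion >= 0), !is.unsorted(rev(criterion))
  )
  out <- tibble::tibble(
    mz = as.numeric(mz),
    criterion = as.numeric(criterion),
    direction = as.character(direction),
    rank = seq_along(mz),
    segment_id = as.integer(segment_id)
  )
  class(out) <- c("ranked_features", class(out))
  out
}
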