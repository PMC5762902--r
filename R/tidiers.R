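#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a registration result
#'
#' One row per transform parameter (`tx`, `ty`, `theta`, `scale`), broom
#' style.
#'
#' @param x A `registration_result` from [register()].
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`.
#' @export
tidy.registration_result <- function(x, ...) {
  tibble::tibble(
    term = c("tx", "ty", "theta", "scale"),
    estimate = c(x$transform$tx, x$transform$ty, x$transform$theta,
                 x$transform$s)
  )
}

#' Glance at a registration result
#'
#' @param x A `registration_result` from [register()].
#' @param ... Unused.
#' @return A one-row tibble: `mse`, `dsc`, `converged`, `n_evals`.
#' @export
glance.registration_result <- function(x, ...) {
  tibble::tibble(mse = x$mse, dsc = x$dsc, converged = x$converged,
                 n_evals = x$n_evals)
}

#' Glance at an acquisition plan
#'
#' @param x An `acquisition_plan` from [make_plan()].
#' @param ... Unused.
#' @return The one-row [reduction_report()] tibble, plus pixel counts.
#' @export
glance.acquisition_plan <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(roi_pixel_count = x$roi_pixel_count,
                   total_pixel_count = x$total_pixel_count),
    reduction_report(x)
  )
}

#' Plot a segment map
#'
#' Raster plot of the cluster index image, background in black, segments on
#' a fixed qualitative palette; physical micrometer axes with y pointing
#' down, matching the image convention.
#'
#' @param object A [segment_map()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.segment_map <- function(object, ...) {
  ctr <- grid_centers(object$grid)
  ctr$label <- factor(as.integer(t(object$labels)), levels = 0:object$k)
  cols <- c("black", segment_palette(object$k))
  names(cols) <- as.character(0:object$k)
  ggplot2::ggplot(ctr, ggplot2::aes(x = .data$x, y = .data$y,
                                    fill = .data$label)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = cols, name = "IDX") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = object$section_id) +
    ggplot2::theme_minimal()
}

#' Plot a ranked feature table
#'
#' Bar chart of criterion scores by m/z, colored by direction.
#'
#' @param object A [ranked_features()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ranked_features <- function(object, ...) {
  df <- as.data.frame(object)
  df$mz_lab <- stats::reorder(sprintf("%.4f", df$mz), -df$rank)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mz_lab, y = .data$criterion,
                                   fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "m/z", y = "criterion score",
                  title = sprintf("segment %d", df$segment_id[1])) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Registration fusion overlay
#'
#' Renders the agreement of a warped moving mask and the fixed mask the way
#' registration quality is usually eyeballed: white where the two masks
#' match on foreground, magenta where exactly one is on, black elsewhere.
#'
#' @param warped,fixed [binary_mask()]s on the same grid.
#' @return A ggplot object.
#' @export
plot_fusion <- function(warped, fixed) {
  stopifnot(grid_equal(warped$grid, fixed$grid))
  ctr <- grid_centers(warped$grid)
  w <- as.logical(t(warped$values)); f <- as.logical(t(fixed$values))
  ctr$state <- dplyr::case_when(w & f ~ "match", xor(w, f) ~ "mismatch",
                                TRUE ~ "background")
  ggplot2::ggplot(ctr, ggplot2::aes(x = .data$x, y = .data$y,
                                    fill = .data$state)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(match = "white",
                                          mismatch = "magenta",
                                          background = "black")) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' Ion image of one binned feature
#'
#' @param ds A binned continuous-mode [msi_dataset()].
#' @param mz Feature m/z; the nearest bin center is shown.
#' @return A ggplot object.
#' @export
plot_ion_image <- function(ds, mz) {
  stopifnot(inherits(ds, "msi_dataset"), ds$mode == "continuous")
  j <- which.min(abs(ds$mz_axis - mz))
  ctr <- grid_centers(ds$grid)
  df <- ctr[match(ds$pixel_idx, ctr$pixel), ]
  df$intensity <- ds$intensities[, j]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = sprintf("m/z %.4f", ds$mz_axis[j])) +
    ggplot2::theme_minimal()
}
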