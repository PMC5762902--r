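#' Physical pixel grid
#'
#' A `pixel_grid` ties an image raster to physical coordinates. Pixels are
#' square, indexed 0-based and row-major, with y increasing downward (image
#' convention). The physical center of pixel `(r, c)` is
#' `origin + (c * pixel_size, r * pixel_size)` in micrometers.
#'
#' @param n_rows,n_cols Raster dimensions (positive integers).
#' @param pixel_size Edge length of a pixel in micrometers (> 0).
#' @param origin Physical `(x, y)` position in micrometers of the center of
#'   pixel `(0, 0)`.
#' @return An object of class `pixel_grid`.
#' @examples
#' g <- pixel_grid(4, 6, pixel_size = 25)
#' grid_to_phys(g, r = 1, c = 2)
#' @export
pixel_grid <- function(n_rows, n_cols, pixel_size, origin = c(0, 0)) {
  stopifnot(
    length(n_rows) == 1, length(n_cols) == 1,
    n_rows >= 1, n_cols >= 1,
    n_rows == as.integer(n_rows), n_cols == as.integer(n_cols),
    is.numeric(pixel_size), length(pixel_size) == 1, pixel_size > 0,
    is.numeric(origin), length(origin) == 2, all(is.finite(origin))
  )
  structure(
    list(
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      pixel_size = as.numeric(pixel_size), origin = as.numeric(origin)
    ),
    class = "pixel_grid"
  )
}

#' @export
print.pixel_grid <- function(x, ...) {
  cat(sprintf(
    "<pixel_grid> %d x %d pixels, %.4g um/px, origin (%.4g, %.4g) um\n",
    x$n_rows, x$n_cols, x$pixel_size, x$origin[1], x$origin[2]
  ))
  invisible(x)
}

#' @export
format.pixel_grid <- function(x, ...) {
  sprintf("%dx%d@%gum", x$n_rows, x$n_cols, x$pixel_size)
}

grid_equal <- function(a, b) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    isTRUE(all.equal(a$pixel_size, b$pixel_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

n_pixels <- function(grid) grid$n_rows * grid$n_cols

#' Map pixel indices to physical coordinates
#'
#' `grid_to_phys()` returns the physical center of pixels `(r, c)` (0-based);
#' `phys_to_grid()` inverts the mapping (continuous, not rounded). The two are
#' exact inverses for on-grid pixel centers.
#'
#' @param grid A [pixel_grid()].
#' @param r,c 0-based row/column indices (vectorized).
#' @param x,y Physical coordinates in micrometers (vectorized).
#' @return A two-column matrix: `(x, y)` in micrometers for `grid_to_phys()`,
#'   continuous `(r, c)` for `phys_to_grid()`.
#' @export
grid_to_phys <- function(grid, r, c) {
  cbind(
    x = grid$origin[1] + c * grid$pixel_size,
    y = grid$origin[2] + r * grid$pixel_size
  )
}

#' @rdname grid_to_phys
#' @export
phys_to_grid <- function(grid, x, y) {
  cbind(
    r = (y - grid$origin[2]) / grid$pixel_size,
    c = (x - grid$origin[1]) / grid$pixel_size
  )
}

#' Pixel-center coordinates of every pixel of a grid
#'
#' @param grid A [pixel_grid()].
#' @return A tibble with 0-based `row`, `col`, linear `pixel` index
#'   (row-major, 0-based) and physical `x`, `y` centers in micrometers.
#' @export
grid_centers <- function(grid) {
  cc <- rep(seq_len(grid$n_cols) - 1L, times = grid$n_rows)
  rr <- rep(seq_len(grid$n_rows) - 1L, each = grid$n_cols)
  p <- grid_to_phys(grid, rr, cc)
  tibble::tibble(
    row = rr, col = cc,
    pixel = rr * grid$n_cols + cc,
    x = p[, 1], y = p[, 2]
  )
}
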