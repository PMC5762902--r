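#' Similarity transform between physical coordinate frames
#'
#' Maps physical points `p` (micrometers) to
#' `center + s * R(theta) %*% (p - center) + (tx, ty)`. Composable and
#' invertible; angles are in degrees, rotation is counterclockwise in the
#' `(x, y-down)` image frame.
#'
#' @param tx,ty Translation in micrometers.
#' @param theta Rotation in degrees.
#' @param s Isotropic scale factor (> 0).
#' @param center Rotation/scaling center `(x, y)` in micrometers.
#' @return An object of class `similarity_transform`.
#' @export
similarity_transform <- function(tx = 0, ty = 0, theta = 0, s = 1,
                                 center = c(0, 0)) {
  stopifnot(s > 0, length(center) == 2)
  structure(
    list(tx = as.numeric(tx), ty = as.numeric(ty), theta = as.numeric(theta),
         s = as.numeric(s), center = as.numeric(center)),
    class = "similarity_transform"
  )
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf(
    "<similarity_transform> t = (%.3g, %.3g) um, theta = %.4g deg, s = %.6g, center = (%.3g, %.3g)\n",
    x$tx, x$ty, x$theta, x$s, x$center[1], x$center[2]
  ))
  invisible(x)
}

#' Apply, invert and compose similarity transforms
#'
#' @param t,a,b [similarity_transform()] objects.
#' @param pts A two-column `(x, y)` matrix of physical points in micrometers.
#' @return `apply_transform()`: the transformed points;
#'   `invert_transform()`: the inverse transform;
#'   `compose_transforms()`: a transform equivalent to applying `b` then `a`.
#' @export
apply_transform <- function(t, pts) {
  pts <- matrix(pts, ncol = 2)
  th <- t$theta * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  ctr <- matrix(t$center, nrow(pts), 2, byrow = TRUE)
  sweep(t$s * (pts - ctr) %*% t(R), 2, c(t$tx, t$ty) + t$center, "+")
}

#' @rdname apply_transform
#' @export
invert_transform <- function(t) {
  th <- -t$theta * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  tt <- -drop(R %*% c(t$tx, t$ty)) / t$s
  similarity_transform(tt[1], tt[2], -t$theta, 1 / t$s, t$center)
}

#' @rdname apply_transform
#' @export
compose_transforms <- function(a, b) {
  # act with b, then a; recover parameters from the action on probe points
  probe <- rbind(c(0, 0), c(1, 0), c(0, 1))
  img <- apply_transform(a, apply_transform(b, probe))
  dx <- img[2, ] - img[1, ]
  s <- sqrt(sum(dx^2))
  theta <- atan2(dx[2], dx[1]) * 180 / pi
  # with center (0,0): p -> s R p + t, so t = image of the origin
  similarity_transform(img[1, 1], img[1, 2], theta, s, center = c(0, 0))
}

#' Dice similarity coefficient of two binary masks
#'
#' `2 |X intersect Y| / (|X| + |Y|)`. Two empty masks are defined as
#' identical (DSC 1) with a warning.
#'
#' @param x,y [binary_mask()]s on the same grid.
#' @return The coefficient, in `[0, 1]`.
#' @export
dice <- function(x, y) {
  stopifnot(inherits(x, "binary_mask"), inherits(y, "binary_mask"))
  if (!grid_equal(x$grid, y$grid)) stop("masks must share one grid")
  nx <- sum(x$values); ny <- sum(y$values)
  if (nx + ny == 0) {
    warning("both masks empty; Dice defined as 1")
    return(1)
  }
  2 * sum(x$values & y$values) / (nx + ny)
}

#' Register a moving binary mask onto a fixed one
#'
#' Intensity-based rigid + isotropic-scale registration: finds the similarity
#' transform minimizing the mean squared error between the warped moving mask
#' and the fixed mask over the fixed grid. Both masks are smoothed with a
#' small Gaussian (sigma 1 px) before the MSE so the piecewise-constant
#' binary objective gains gradients; optimization is derivative-free
#' Nelder-Mead over a coarse-to-fine pyramid (x4, x2, x1), initialized by
#' centroid alignment and the square root of the area ratio.
#'
#' @param moving,fixed Non-empty [binary_mask()]s (grids may differ in size
#'   and pixel pitch; everything happens in physical micrometers).
#' @param levels Pyramid downsampling factors, coarse to fine.
#' @param sigma_px Gaussian smoothing width in (level) pixels.
#' @param tol Relative convergence tolerance on the normalized MSE.
#' @param max_eval Maximum objective evaluations per pyramid level.
#' @return An object of class `registration_result`: fields `transform`
#'   (moving to fixed frame), `mse`, `dsc` (Dice after re-binarizing the
#'   warp), `converged`, `n_evals`.
#' @export
register <- function(moving, fixed, levels = c(4, 2, 1), sigma_px = 1,
                     tol = 1e-4, max_eval = 400) {
  stopifnot(inherits(moving, "binary_mask"), inherits(fixed, "binary_mask"))
  if (sum(moving$values) == 0 || sum(fixed$values) == 0) {
    stop("cannot register empty masks")
  }
  cm <- mask_centroid(moving)
  cf <- mask_centroid(fixed)
  s0 <- sqrt((sum(fixed$values) * fixed$grid$pixel_size^2) /
               (sum(moving$values) * moving$grid$pixel_size^2))
  par <- c(cf - cm, 0, s0) # tx, ty, theta, s ; center = moving centroid
  n_evals <- 0L
  conv <- FALSE
  value <- NA_real_
  for (lv in levels) {
    mv <- mask_pyramid(moving, lv)
    fx <- mask_pyramid(fixed, lv)
    mv_img <- gauss_blur(mv$img, sigma_px)
    fx_img <- gauss_blur(fx$img, sigma_px)
    fx_pts <- as.matrix(grid_centers(fx$grid)[, c("x", "y")])
    fx_vals <- as.numeric(t(fx_img)) # row-major, matching grid_centers order
    sc <- c(fx$grid$pixel_size, fx$grid$pixel_size, 2, 0.02)
    obj <- function(q) {
      n_evals <<- n_evals + 1L
      tr <- similarity_transform(q[1] * sc[1], q[2] * sc[2], q[3] * sc[3],
                                 max(1 + q[4] * sc[4], 1e-3), center = cm)
      src <- apply_transform(invert_transform(tr), fx_pts)
      w <- sample_bilinear(mv_img, mv$grid, src)
      mean((w - fx_vals)^2)
    }
    q0 <- c(par[1] / sc[1], par[2] / sc[2], par[3] / sc[3],
            (par[4] - 1) / sc[4])
    opt <- stats::optim(q0, obj, method = "Nelder-Mead",
                        control = list(reltol = tol, maxit = max_eval))
    par <- c(opt$par[1] * sc[1], opt$par[2] * sc[2], opt$par[3] * sc[3],
             max(1 + opt$par[4] * sc[4], 1e-3))
    conv <- opt$convergence == 0
    value <- opt$value
  }
  tr <- similarity_transform(par[1], par[2], par[3], par[4], center = cm)
  warped <- warp_mask(moving, tr, fixed$grid)
  res <- structure(
    list(transform = tr, mse = value, dsc = dice(warped, fixed),
         converged = conv, n_evals = n_evals),
    class = "registration_result"
  )
  res
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf(
    "<registration_result> mse = %.4g, DSC = %.4f, %s after %d evaluations\n",
    x$mse, x$dsc, if (x$converged) "converged" else "NOT converged", x$n_evals
  ))
  print(x$transform)
  invisible(x)
}

mask_centroid <- function(mask) {
  idx <- which(mask$values, arr.ind = TRUE)
  p <- grid_to_phys(mask$grid, idx[, 1] - 1, idx[, 2] - 1)
  colMeans(p)
}

# block-mean downsample by integer factor; grid geometry follows
mask_pyramid <- function(mask, factor) {
  img <- mask$values * 1
  g <- mask$grid
  if (factor > 1) {
    nr <- floor(nrow(img) / factor) * factor
    nc <- floor(ncol(img) / factor) * factor
    img <- img[seq_len(nr), seq_len(nc), drop = FALSE]
    img <- block_mean(img, factor)
    g <- pixel_grid(nrow(img), ncol(img), g$pixel_size * factor,
                    g$origin + g$pixel_size * (factor - 1) / 2)
  }
  list(img = img, grid = g)
}

block_mean <- function(img, f) {
  nr <- nrow(img) / f; nc <- ncol(img) / f
  x <- array(img, c(f, nr, f, nc))
  apply(x, c(2, 4), mean)
}

gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- ceiling(3 * sigma)
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(m) { # along rows (first dim), replicate padding
    nr <- nrow(m)
    pad <- rbind(m[rep(1, r), , drop = FALSE], m, m[rep(nr, r), , drop = FALSE])
    out <- 0 * m
    for (i in seq_along(k)) out <- out + k[i] * pad[i:(i + nr - 1), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(img))))
}

# bilinear sampling of image at physical points; outside the grid -> 0
sample_bilinear <- function(img, grid, pts) {
  rc <- phys_to_grid(grid, pts[, 1], pts[, 2])
  r <- rc[, 1]; c <- rc[, 2]
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  nr <- nrow(img); nc <- ncol(img)
  val <- function(ri, ci) {
    ok <- ri >= 0 & ri <= nr - 1 & ci >= 0 & ci <= nc - 1
    out <- numeric(length(ri))
    out[ok] <- img[cbind(ri[ok] + 1, ci[ok] + 1)]
    out
  }
  val(r0, c0) * (1 - fr) * (1 - fc) +
    val(r0 + 1, c0) * fr * (1 - fc) +
    val(r0, c0 + 1) * (1 - fr) * fc +
    val(r0 + 1, c0 + 1) * fr * fc
}

# warp a binary mask onto a target grid through t (moving -> target frame)
warp_mask <- function(mask, t, target_grid) {
  pts <- as.matrix(grid_centers(target_grid)[, c("x", "y")])
  src <- apply_transform(invert_transform(t), pts)
  v <- sample_bilinear(mask$values * 1, mask$grid, src)
  binary_mask(target_grid,
              matrix(v > 0.5, target_grid$n_rows, target_grid$n_cols,
                     byrow = TRUE))
}

#' Transfer a segment mask onto another pixel grid
#'
#' Pulls every target pixel back through the inverse transform and assigns
#' it the majority label over a supersampled footprint (a `supersample` x
#' `supersample` lattice of points inside the target pixel, each looked up
#' in the source label image by nearest pixel). The returned mask is TRUE
#' where the majority label equals `idx`. Majority voting, rather than
#' nearest-neighbor at the center, is what makes transfers onto 2-12x
#' coarser MSI grids well-behaved.
#'
#' @param seg A [segment_map()] in the source (FTIR) frame.
#' @param idx Segment index to transfer.
#' @param t A [similarity_transform()] mapping source to target physical
#'   coordinates.
#' @param target A [pixel_grid()] (MSI/optical frame).
#' @param supersample Lattice side length per target pixel (default 4).
#' @return A [binary_mask()] on `target`; warns if the segment lands
#'   entirely outside the target extent.
#' @export
transfer_segment <- function(seg, idx, t, target, supersample = 4L) {
  stopifnot(inherits(seg, "segment_map"), inherits(target, "pixel_grid"))
  ss <- as.integer(supersample)
  ctr <- grid_centers(target)
  offs <- ((seq_len(ss) - 0.5) / ss - 0.5) * target$pixel_size
  votes <- matrix(0L, nrow(ctr), ss * ss) # sampled labels per target pixel
  inv <- invert_transform(t)
  kk <- 0L
  for (oy in offs) for (ox in offs) {
    kk <- kk + 1L
    src <- apply_transform(inv, cbind(ctr$x + ox, ctr$y + oy))
    rc <- phys_to_grid(seg$grid, src[, 1], src[, 2])
    ri <- round(rc[, 1]); ci <- round(rc[, 2])
    ok <- ri >= 0 & ri < seg$grid$n_rows & ci >= 0 & ci < seg$grid$n_cols
    lab <- integer(nrow(ctr))
    lab[ok] <- seg$labels[cbind(ri[ok] + 1, ci[ok] + 1)]
    votes[, kk] <- lab
  }
  maj <- apply(votes, 1, function(v) {
    tb <- tabulate(v + 1L)
    which.max(tb) - 1L # ties resolve to the smallest label
  })
  vals <- matrix(maj == as.integer(idx), target$n_rows, target$n_cols,
                 byrow = TRUE)
  if (!any(vals) && any(seg$labels == idx)) {
    warning("transferred segment lies entirely outside the target grid")
  }
  binary_mask(target, vals)
}

#' Split an MSI dataset's spectra by a region of interest
#'
#' Partitions the populated pixels into those inside and outside a binary
#' mask on the same grid. Pixel counts are conserved:
#' `inside + outside = populated`.
#'
#' @param ds An [msi_dataset()].
#' @param roi A [binary_mask()] on the dataset's grid.
#' @return A list of two [msi_dataset()]s, `inside` and `outside`.
#' @export
extract_segment_spectra <- function(ds, roi) {
  stopifnot(inherits(ds, "msi_dataset"), inherits(roi, "binary_mask"))
  if (!grid_equal(ds$grid, roi$grid)) stop("ROI must live on the dataset grid")
  rv <- as.logical(t(roi$values)) # row-major, matching pixel_idx order
  inside <- rv[ds$pixel_idx + 1L]
  list(inside = subset_msi(ds, inside), outside = subset_msi(ds, !inside))
}

subset_msi <- function(ds, keep) {
  if (ds$mode == "continuous") {
    msi_dataset(ds$grid, ds$pixel_idx[keep], mode = "continuous",
                mz_axis = ds$mz_axis,
                intensities = ds$intensities[keep, , drop = FALSE],
                polarity = ds$polarity, section_id = ds$section_id)
  } else {
    msi_dataset(ds$grid, ds$pixel_idx[keep], mode = "processed",
                peaks = ds$peaks[keep], polarity = ds$polarity,
                section_id = ds$section_id)
  }
}
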