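#' Segmentation configuration
#'
#' @param k Number of clusters (segments).
#' @param n_init Number of k-means++ restarts; the run with the lowest
#'   within-cluster sum of squares wins (default 5).
#' @param max_iter Maximum Lloyd iterations per restart (default 100).
#' @param seed RNG seed; fixes seeding and restarts, so repeated runs are
#'   bit-identical (default 1).
#' @param spatial_radius Neighborhood radius in pixels for spatially aware
#'   clustering; 0 disables smoothing (default 3).
#' @param spatial_sigma Gaussian width in pixels; defaults to
#'   `spatial_radius / 2` so the kernel has effectively vanished at the
#'   truncation radius.
#' @return A list of class `seg_config`.
#' @export
seg_config <- function(k, n_init = 5, max_iter = 100, seed = 1L,
                       spatial_radius = 3, spatial_sigma = spatial_radius / 2) {
  stopifnot(k >= 1, n_init >= 1, max_iter >= 1, spatial_radius >= 0)
  structure(
    list(k = as.integer(k), n_init = as.integer(n_init),
         max_iter = as.integer(max_iter), seed = as.integer(seed),
         spatial_radius = spatial_radius,
         spatial_sigma = max(spatial_sigma, 1e-9)),
    class = "seg_config"
  )
}

# k-means++ (D^2 seeding) + Lloyd with deterministic empty-cluster reseeding.
# Restarts share one RNG stream started at `seed`; best WSS wins.
kmeanspp_fit <- function(X, k, seed = 1L, n_init = 5L, max_iter = 100L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k > n) stop(sprintf("k = %d exceeds the number of points (%d)", k, n))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  xsq <- rowSums(X^2)
  best <- NULL
  for (rep in seq_len(n_init)) {
    centers <- matrix(0, k, ncol(X))
    ci <- sample.int(n, 1)
    centers[1, ] <- X[ci, ]
    if (k > 1) {
      d2 <- pmax(xsq + sum(centers[1, ]^2) - 2 * drop(X %*% centers[1, ]), 0)
      for (j in 2:k) {
        if (sum(d2) <= 0) {
          ci <- sample.int(n, 1)
        } else {
          ci <- sample.int(n, 1, prob = d2)
        }
        centers[j, ] <- X[ci, ]
        d2 <- pmin(d2, pmax(
          xsq + sum(centers[j, ]^2) - 2 * drop(X %*% centers[j, ]), 0))
      }
    }
    fit <- lloyd(X, centers, xsq, max_iter)
    if (is.null(best) || fit$wss < best$wss) best <- fit
  }
  best
}

lloyd <- function(X, centers, xsq, max_iter) {
  n <- nrow(X); k <- nrow(centers)
  assign_prev <- integer(n)
  for (it in seq_len(max_iter)) {
    D <- outer(xsq, rowSums(centers^2), "+") - 2 * X %*% t(centers)
    cl <- max.col(-D, ties.method = "first")
    # empty clusters: reseed from the point farthest from its centroid
    dmin <- D[cbind(seq_len(n), cl)]
    for (j in seq_len(k)) {
      if (!any(cl == j)) {
        far <- which.max(dmin)
        centers[j, ] <- X[far, ]
        cl[far] <- j
        dmin[far] <- 0
      }
    }
    if (identical(cl, assign_prev)) break
    assign_prev <- cl
    for (j in seq_len(k)) centers[j, ] <- colMeans(X[cl == j, , drop = FALSE])
  }
  D <- outer(xsq, rowSums(centers^2), "+") - 2 * X %*% t(centers)
  cl <- max.col(-D, ties.method = "first")
  wss <- sum(pmax(D[cbind(seq_len(n), cl)], 0))
  list(cluster = cl, centers = centers, wss = wss)
}

# renumber clusters 1..k by descending member count (ties: smaller centroid
# norm, then original index) -- makes labels stable across runs
canonicalize_labels <- function(cl, centers) {
  k <- nrow(centers)
  counts <- tabulate(cl, nbins = k)
  ord <- order(-counts, rowSums(centers^2), seq_len(k))
  remap <- integer(k)
  remap[ord] <- seq_len(k)
  list(cluster = remap[cl], centers = centers[ord, , drop = FALSE])
}

#' Joint k-means++ segmentation of FTIR cubes
#'
#' Pools the on-tissue spectra of all sections and partitions them with a
#' single k-means++ run, so a cluster index (IDX) means the same tissue class
#' in every section. Clusters are renumbered 1..k by descending pooled size;
#' background pixels keep label 0. Sections are pooled in sorted
#' `section_id` order, which makes the result invariant to the order the
#' cubes are passed in.
#'
#' @param cubes A list of preprocessed [hyper_cube()]s sharing one retained
#'   wavenumber axis, with unique `section_id`s.
#' @param cfg A [seg_config()].
#' @return A named list of [segment_map()]s, one per section (input order).
#' @export
kmeanspp_joint <- function(cubes, cfg) {
  if (inherits(cubes, "hyper_cube")) cubes <- list(cubes)
  stopifnot(length(cubes) >= 1)
  ids <- vapply(cubes, function(x) x$section_id, "")
  if (anyDuplicated(ids)) stop("section_id must be unique across cubes")
  wn0 <- cubes[[1]]$wavenumbers
  for (cb in cubes) {
    if (length(cb$wavenumbers) != length(wn0) ||
        max(abs(cb$wavenumbers - wn0)) > 1e-9) {
      stop("all cubes must share an identical retained wavenumber axis")
    }
  }
  ord <- order(ids)
  pooled <- do.call(rbind, lapply(cubes[ord], function(cb) {
    cb$data[cube_tissue_idx(cb), , drop = FALSE]
  }))
  if (cfg$k > nrow(pooled)) stop("k exceeds the number of pooled tissue pixels")
  fit <- kmeanspp_fit(pooled, cfg$k, seed = cfg$seed,
                      n_init = cfg$n_init, max_iter = cfg$max_iter)
  can <- canonicalize_labels(fit$cluster, fit$centers)
  out <- vector("list", length(cubes))
  names(out) <- ids
  pos <- 0
  for (oi in ord) {
    cb <- cubes[[oi]]
    ti <- cube_tissue_idx(cb)
    lab_vec <- integer(n_pixels(cb$grid))
    lab_vec[ti] <- can$cluster[pos + seq_along(ti)]
    pos <- pos + length(ti)
    out[[cb$section_id]] <- segment_map(
      cb$grid,
      matrix(lab_vec, cb$grid$n_rows, cb$grid$n_cols, byrow = TRUE),
      cfg$k, section_id = cb$section_id
    )
  }
  out[ids]
}

#' Binary tissue shape from an image or cube
#'
#' Splits pixel intensities (total absolute signal for a cube) into two
#' groups by k = 2 clustering. The foreground is the group whose mean
#' intensity deviates more from the image border's mean intensity — tissue
#' sits away from the slide border, so this choice is invariant to contrast
#' inversion. Optionally only the largest connected components are kept.
#'
#' @param x A numeric matrix (single-channel image) or a [hyper_cube()].
#' @param n_components Keep the `n_components` largest 4-connected
#'   foreground components (default `Inf`, keep all).
#' @param pixel_size,origin Grid geometry when `x` is a bare matrix.
#' @param seed RNG seed for the 2-means split.
#' @return A [binary_mask()].
#' @export
tissue_shape_mask <- function(x, n_components = Inf, pixel_size = 1,
                              origin = c(0, 0), seed = 1L) {
  if (inherits(x, "hyper_cube")) {
    img <- matrix(rowSums(abs(x$data)), x$grid$n_rows, x$grid$n_cols,
                  byrow = TRUE)
    grid <- x$grid
  } else {
    img <- as.matrix(x)
    grid <- pixel_grid(nrow(img), ncol(img), pixel_size, origin)
  }
  v <- as.numeric(img)
  if (stats::sd(v) == 0) stop("constant image has no tissue/background split")
  km <- kmeanspp_fit(matrix(v, ncol = 1), k = 2, seed = seed, n_init = 3,
                    max_iter = 50)
  nr <- nrow(img); nc <- ncol(img)
  border_mean <- mean(c(img[1, ], img[nr, ], img[, 1], img[, nc]))
  m1 <- mean(v[km$cluster == 1]); m2 <- mean(v[km$cluster == 2])
  fg <- if (abs(m1 - border_mean) >= abs(m2 - border_mean)) 1L else 2L
  vals <- matrix(km$cluster == fg, nr, nc)
  if (is.finite(n_components)) {
    lab <- EBImage::bwlabel(vals)
    sizes <- tabulate(lab[lab > 0])
    keep <- order(sizes, decreasing = TRUE)[seq_len(min(n_components,
                                                        length(sizes)))]
    vals <- matrix(lab %in% keep, nr, nc)
  }
  binary_mask(grid, vals)
}

#' Spatially aware clustering of a binned MSI dataset
#'
#' Replaces each populated pixel's feature vector by the Gaussian-weighted
#' mean of its neighborhood (width `spatial_sigma`, truncated at
#' `spatial_radius` pixels; absent neighbors are excluded and the weights
#' renormalized), then runs the same k-means++ as [kmeanspp_joint()]. With
#' radius 0 this reduces exactly to plain k-means++ clustering.
#'
#' @param ds A continuous-mode (binned) [msi_dataset()].
#' @param cfg A [seg_config()].
#' @return A [segment_map()] on the MSI grid; absent pixels are labeled 0.
#' @export
spatially_aware_cluster <- function(ds, cfg) {
  stopifnot(inherits(ds, "msi_dataset"), ds$mode == "continuous")
  X <- smooth_features(ds, cfg$spatial_radius, cfg$spatial_sigma)
  if (cfg$k > nrow(X)) stop("k exceeds the number of populated pixels")
  fit <- kmeanspp_fit(X, cfg$k, seed = cfg$seed, n_init = cfg$n_init,
                      max_iter = cfg$max_iter)
  can <- canonicalize_labels(fit$cluster, fit$centers)
  lab_vec <- integer(n_pixels(ds$grid))
  lab_vec[ds$pixel_idx + 1L] <- can$cluster
  segment_map(ds$grid,
              matrix(lab_vec, ds$grid$n_rows, ds$grid$n_cols, byrow = TRUE),
              cfg$k, section_id = ds$section_id)
}

# Gaussian neighborhood smoothing of the pixel-by-feature matrix, absent
# neighbors excluded, weights renormalized per pixel.
smooth_features <- function(ds, radius, sigma) {
  X <- ds$intensities
  if (radius <= 0) return(X)
  nr <- ds$grid$n_rows; nc <- ds$grid$n_cols; nf <- ncol(X)
  pop <- matrix(FALSE, nr, nc)
  pop[cbind(ds$pixel_idx %/% nc + 1L, ds$pixel_idx %% nc + 1L)] <- TRUE
  # feature images, populated pixels only
  imgs <- array(0, c(nr, nc, nf))
  rr <- ds$pixel_idx %/% nc + 1L
  cc <- ds$pixel_idx %% nc + 1L
  for (f in seq_len(nf)) imgs[, , f][cbind(rr, cc)] <- X[, f]
  acc <- array(0, c(nr, nc, nf))
  wsum <- matrix(0, nr, nc)
  r_int <- floor(radius)
  for (dy in -r_int:r_int) for (dx in -r_int:r_int) {
    d2 <- dy^2 + dx^2
    if (d2 > radius^2) next
    w <- exp(-d2 / (2 * sigma^2))
    ry <- max(1, 1 - dy):min(nr, nr - dy) # destination rows
    rx <- max(1, 1 - dx):min(nc, nc - dx)
    src_pop <- pop[ry + dy, rx + dx, drop = FALSE]
    wsum[ry, rx] <- wsum[ry, rx] + w * src_pop
    for (f in seq_len(nf)) {
      acc[, , f][ry, rx] <- acc[, , f][ry, rx] +
        w * imgs[ry + dy, rx + dx, f] * src_pop
    }
  }
  out <- matrix(0, nrow(X), nf)
  wv <- wsum[cbind(rr, cc)]
  for (f in seq_len(nf)) out[, f] <- acc[, , f][cbind(rr, cc)] / wv
  out
}

#' Trace the boundary contours of a segment
#'
#' Returns closed polygons (in physical micrometers) tracing the boundary of
#' `{labels == idx}` along pixel edges. Outer rings and hole rings have
#' opposite orientation, so the signed polygon areas sum exactly to
#' `pixel count * pixel_size^2`.
#'
#' @param seg A [segment_map()] (or a [binary_mask()], with `idx` ignored).
#' @param idx Segment index to trace.
#' @return A tibble with columns `ring`, `vertex`, `x`, `y`; each ring is
#'   closed (last vertex repeats the first).
#' @export
segment_contour <- function(seg, idx = 1L) {
  if (inherits(seg, "binary_mask")) {
    on <- seg$values
    grid <- seg$grid
  } else {
    stopifnot(inherits(seg, "segment_map"))
    on <- seg$labels == as.integer(idx)
    grid <- seg$grid
  }
  if (!any(on)) {
    return(tibble::tibble(ring = integer(0), vertex = integer(0),
                          x = numeric(0), y = numeric(0)))
  }
  nr <- nrow(on); nc <- ncol(on)
  padded <- matrix(FALSE, nr + 2, nc + 2)
  padded[2:(nr + 1), 2:(nc + 1)] <- on
  # directed boundary edges between corner nodes (i, j), 0-based corners
  onr <- which(on, arr.ind = TRUE)
  es <- matrix(0L, 0, 4) # (i0, j0, i1, j1)
  for (t in seq_len(nrow(onr))) {
    r <- onr[t, 1] - 1L; c <- onr[t, 2] - 1L # 0-based pixel
    pr <- r + 2L; pc <- c + 2L
    add <- NULL
    if (!padded[pr - 1, pc]) add <- rbind(add, c(r, c, r, c + 1L))       # top
    if (!padded[pr, pc + 1]) add <- rbind(add, c(r, c + 1L, r + 1L, c + 1L)) # right
    if (!padded[pr + 1, pc]) add <- rbind(add, c(r + 1L, c + 1L, r + 1L, c)) # bottom
    if (!padded[pr, pc - 1]) add <- rbind(add, c(r + 1L, c, r, c))       # left
    if (!is.null(add)) es <- rbind(es, add)
  }
  key <- function(i, j) i * (nc + 2L) + j
  from <- key(es[, 1], es[, 2])
  used <- rep(FALSE, nrow(es))
  lookup <- split(seq_len(nrow(es)), from)
  rings <- list()
  for (e0 in seq_len(nrow(es))) {
    if (used[e0]) next
    ring_i <- es[e0, 1]; ring_j <- es[e0, 2]
    cur <- e0
    verts_i <- es[e0, 1]; verts_j <- es[e0, 2]
    repeat {
      used[cur] <- TRUE
      ni <- es[cur, 3]; nj <- es[cur, 4]
      verts_i <- c(verts_i, ni); verts_j <- c(verts_j, nj)
      if (ni == ring_i && nj == ring_j) break
      cand <- lookup[[as.character(key(ni, nj))]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0) break # should not happen on valid edge sets
      if (length(cand) > 1) {
        # junction corner (diagonally touching pixels): take the turn that
        # hugs the current pixel, keeping 4-connected components as
        # separate rings; with (row, col) axes and y down that is the
        # minimum-cross-product turn
        din <- c(es[cur, 3] - es[cur, 1], es[cur, 4] - es[cur, 2])
        cross <- vapply(cand, function(e) {
          dout <- c(es[e, 3] - es[e, 1], es[e, 4] - es[e, 2])
        din[1] * dout[2] - din[2] * dout[1]
        }, 0)
        cand <- cand[which.min(cross)]
      }
      cur <- cand[1]
    }
    rings[[length(rings) + 1]] <- cbind(verts_i, verts_j)
  }
  ps <- grid$pixel_size
  out <- purrr::imap_dfr(rings, function(rg, k) {
    tibble::tibble(
      ring = as.integer(k),
      vertex = seq_len(nrow(rg)),
      x = unname(grid$origin[1] + (rg[, 2] - 0.5) * ps),
      y = unname(grid$origin[2] + (rg[, 1] - 0.5) * ps)
    )
  })
  out
}

#' Signed area of traced contours
#'
#' Shoelace area per ring of a [segment_contour()] tibble; outer rings are
#' positive and holes negative, so the total equals the segment's pixel area.
#'
#' @param contour A tibble from [segment_contour()].
#' @return A tibble with `ring` and signed `area` (square micrometers).
#' @export
contour_area <- function(contour) {
  dplyr::summarise(
    dplyr::group_by(contour, .data$ring),
    area = {
      n <- dplyr::n()
      xx <- .data$x; yy <- .data$y
      # edges are traced clockwise on screen (y down), which makes the
      # shoelace sum of outer rings positive and of holes negative
      sum(xx[-n] * yy[-1] - xx[-1] * yy[-n]) / 2
    },
    .groups = "drop"
  )
}
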