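#' Read and write binary masks
#'
#' Masks travel either as strictly two-valued 8-bit grayscale PNGs
#' (0 = background, 255 = foreground) or as CSV label matrices (0/1, no
#' header). PNG carries no physical geometry, so `pixel_size`/`origin` must
#' be supplied on read when they matter.
#'
#' @param mask A [binary_mask()].
#' @param path Output path ending in `.png` or `.csv`.
#' @return `path` invisibly for the writer; a [binary_mask()] for the reader.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(matrix(as.numeric(mask$values),
                         nrow = mask$grid$n_rows), path)
  } else {
    utils::write.table(mask$values * 1L, path, sep = ",",
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_mask
#' @param pixel_size,origin Grid geometry to attach on read.
#' @export
read_mask <- function(path, pixel_size = 1, origin = c(0, 0)) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    vals <- img > 0.5
  } else {
    vals <- as.matrix(utils::read.csv(path, header = FALSE)) > 0.5
    dimnames(vals) <- NULL
  }
  binary_mask(pixel_grid(nrow(vals), ncol(vals), pixel_size, origin), vals)
}

#' Write and read segment maps
#'
#' The CSV carries the raw integer label matrix (lossless round-trip); the
#' PNG is a color-coded visualization (background black, segments on a fixed
#' qualitative palette).
#'
#' @param seg A [segment_map()].
#' @param path Output path (`.csv` for the label matrix, `.png` for the
#'   color rendering).
#' @return `path` invisibly; `read_segment_map()` returns a [segment_map()].
#' @export
write_segment_map <- function(seg, path) {
  stopifnot(inherits(seg, "segment_map"))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    pal <- segment_palette(seg$k)
    rgb <- array(0, c(seg$grid$n_rows, seg$grid$n_cols, 3))
    for (i in seq_len(seg$k)) {
      hit <- seg$labels == i
      col <- grDevices::col2rgb(pal[i]) / 255
      for (ch in 1:3) rgb[, , ch][hit] <- col[ch]
    }
    png::writePNG(rgb, path)
  } else {
    utils::write.table(seg$labels, path, sep = ",",
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_segment_map
#' @param k Segment count; defaults to the maximum label present.
#' @param pixel_size,origin Grid geometry to attach on read.
#' @export
read_segment_map <- function(path, k = NULL, pixel_size = 1, origin = c(0, 0)) {
  labels <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(labels) <- NULL
  storage.mode(labels) <- "integer"
  segment_map(
    pixel_grid(nrow(labels), ncol(labels), pixel_size, origin),
    labels, k %||% max(labels)
  )
}

segment_palette <- function(k) {
  base <- c(
    "#E41A1C", "#377EB8", "#4DAF4A", "#984EA3", "#FF7F00",
    "#FFFF33", "#A65628", "#F781BF", "#999999", "#66C2A5",
    "#FC8D62", "#8DA0CB", "#E78AC3", "#A6D854", "#FFD92F"
  )
  rep_len(base, k)
}

#' Write and read ranked feature tables
#'
#' CSV with header `mz,criterion,direction,rank,segment_id`, rows in rank
#' order.
#'
#' @param t A [ranked_features()] tibble.
#' @param path Output CSV path.
#' @return `path` invisibly; the reader returns a [ranked_features()] tibble.
#' @export
write_feature_table <- function(t, path) {
  stopifnot(all(c("mz", "criterion", "direction", "rank", "segment_id")
                %in% names(t)))
  utils::write.csv(
    as.data.frame(t)[, c("mz", "criterion", "direction", "rank", "segment_id")],
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path)
  if (nrow(df) == 0) {
    return(ranked_features(numeric(0), numeric(0), character(0), integer(1)[0]))
  }
  ranked_features(df$mz, df$criterion, df$direction, df$segment_id[1])
}

#' Write and read similarity transforms as JSON
#'
#' The JSON schema is `{tx, ty, theta_deg, scale, center: [x, y]}`, all in
#' micrometers except the angle (degrees).
#'
#' @param t A [similarity_transform()].
#' @param path Output `.json` path.
#' @return `path` invisibly; the reader returns a [similarity_transform()].
#' @export
write_transform <- function(t, path) {
  stopifnot(inherits(t, "similarity_transform"))
  jsonlite::write_json(
    list(tx = t$tx, ty = t$ty, theta_deg = t$theta, scale = t$s,
         center = t$center),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  similarity_transform(j$tx, j$ty, j$theta_deg, j$scale, j$center)
}
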