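#' Build an acquisition plan from a region of interest
#'
#' Turns a transferred segment mask into a targeted-acquisition plan: ROI
#' boundary polygons (traced with [segment_contour()]), pixel counts on the
#' acquisition grid, and per-pixel acquisition costs from which
#' [reduction_report()] derives the data-load and time savings. Per-pixel
#' cost is modeled as constant, so savings are set purely by the segment's
#' size relative to the whole tissue.
#'
#' @param roi Non-empty [binary_mask()] of the pixels to acquire.
#' @param tissue [binary_mask()] of the full tissue region on the same grid.
#' @param time_per_pixel Acquisition time per pixel, seconds.
#' @param data_per_pixel Data volume per pixel, bytes.
#' @return An object of class `acquisition_plan`.
#' @export
make_plan <- function(roi, tissue, time_per_pixel = 1, data_per_pixel = 1) {
  stopifnot(inherits(roi, "binary_mask"), inherits(tissue, "binary_mask"))
  if (!grid_equal(roi$grid, tissue$grid)) stop("ROI and tissue must share a grid")
  if (sum(roi$values) == 0) stop("ROI is empty; nothing to acquire")
  if (any(roi$values & !tissue$values)) {
    roi <- binary_mask(roi$grid, roi$values & tissue$values)
    if (sum(roi$values) == 0) stop("ROI lies entirely off tissue")
  }
  structure(
    list(
      roi = roi,
      roi_polygons = segment_contour(roi),
      roi_pixel_count = sum(roi$values),
      total_pixel_count = sum(tissue$values),
      time_per_pixel = time_per_pixel,
      data_per_pixel = data_per_pixel
    ),
    class = "acquisition_plan"
  )
}

#' @export
print.acquisition_plan <- function(x, ...) {
  r <- reduction_report(x)
  cat(sprintf(
    "<acquisition_plan> %d / %d pixels (%.1f%% time and data reduction)\n",
    x$roi_pixel_count, x$total_pixel_count, 100 * r$time_reduction
  ))
  invisible(x)
}

#' Data-load and acquisition-time reduction of a plan
#'
#' `reduction = 1 - roi_pixels / total_pixels`, identical for time and data
#' under the constant per-pixel cost model; estimated time and data are the
#' ROI pixel count times the per-pixel costs.
#'
#' @param plan An [make_plan()] result.
#' @return A one-row tibble: `data_reduction`, `time_reduction` (fractions
#'   in `[0, 1]`), `est_time` (seconds), `est_data` (bytes).
#' @export
reduction_report <- function(plan) {
  stopifnot(inherits(plan, "acquisition_plan"))
  red <- (plan$total_pixel_count - plan$roi_pixel_count) /
    plan$total_pixel_count
  tibble::tibble(
    data_reduction = red,
    time_reduction = red,
    est_time = plan$roi_pixel_count * plan$time_per_pixel,
    est_data = plan$roi_pixel_count * plan$data_per_pixel
  )
}

#' Export ROI geometry for an external acquisition tool
#'
#' Writes the plan's ROI outline either as polygon JSON (one closed ring per
#' connected component, `{x, y}` vertex arrays in micrometers in the target
#' frame, y increasing downward) or as a CSV vertex list with columns
#' `ring,vertex,x,y`.
#'
#' @param plan An [make_plan()] result.
#' @param path Output path.
#' @param dialect `"polygon-json"` or `"csv-vertex-list"` (default by file
#'   extension).
#' @return `path`, invisibly.
#' @export
export_roi <- function(plan, path,
                       dialect = c("auto", "polygon-json", "csv-vertex-list")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE))
      "csv-vertex-list" else "polygon-json"
  }
  poly <- plan$roi_polygons
  if (dialect == "csv-vertex-list") {
    utils::write.csv(as.data.frame(poly), path, row.names = FALSE,
                     quote = FALSE)
  } else {
    rings <- lapply(split(poly, poly$ring), function(rg) {
      list(x = rg$x, y = rg$y)
    })
    jsonlite::write_json(
      list(units = "micrometer", axis = "y-down", rings = unname(rings)),
      path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' Read ROI polygons back
#'
#' @param path A file written by [export_roi()].
#' @return A contour tibble (`ring`, `vertex`, `x`, `y`).
#' @export
read_roi <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path)
    return(tibble::as_tibble(df))
  }
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  purrr::imap_dfr(j$rings, function(rg, k) {
    tibble::tibble(ring = as.integer(k), vertex = seq_along(rg$x),
                   x = as.numeric(unlist(rg$x)),
                   y = as.numeric(unlist(rg$y)))
  })
}

#' Run the whole FTIR-guided MSI workflow
#'
#' Orchestrates preprocess, joint segmentation, target-segment selection,
#' tissue-shape registration, segment transfer, and then either feature
#' ranking (`mode = "interpretation"`) or ROI planning (`mode = "guidance"`).
#' The target segment is chosen explicitly (`target_idx`) or as the segment
#' with maximum Dice overlap against a reference mask registered into the
#' FTIR frame. Every artifact is written under `out_dir` along with a
#' manifest recording the configuration and seeds, sufficient to regenerate
#' the run.
#'
#' @param cubes A [hyper_cube()] or list of them (raw, unprocessed).
#' @param msi An [msi_dataset()] (continuous profile mode) for
#'   interpretation mode, or NULL in guidance mode.
#' @param fixed_mask [binary_mask()] of the tissue in the target
#'   (optical/MSI) frame; computed from `msi` TICs if omitted.
#' @param mode `"interpretation"` or `"guidance"`.
#' @param k Number of segments.
#' @param target_idx Segment to transfer; if `NULL`, chosen by maximum Dice
#'   against `reference_mask` (which is then required).
#' @param reference_mask Optional [binary_mask()] in the target frame used
#'   to pick the target segment.
#' @param ftir_cfg,seg_cfg,msi_cfg Stage configurations.
#' @param time_per_pixel,data_per_pixel Acquisition costs for guidance mode.
#' @param out_dir Output directory for artifacts; `NULL` keeps everything
#'   in memory.
#' @param seed Seed recorded in the manifest and used for clustering.
#' @return A list with the segment maps, registration result, transferred
#'   mask, and the mode's product (`features` or `plan` + `report`).
#' @export
run_pipeline <- function(cubes, msi = NULL, fixed_mask = NULL,
                         mode = c("interpretation", "guidance"),
                         k = 10, target_idx = NULL, reference_mask = NULL,
                         ftir_cfg = ftir_config(), seg_cfg = NULL,
                         msi_cfg = msi_config(),
                         time_per_pixel = 1, data_per_pixel = 1,
                         out_dir = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (inherits(cubes, "hyper_cube")) cubes <- list(cubes)
  if (is.null(seg_cfg)) seg_cfg <- seg_config(k, seed = seed)

  pp <- lapply(cubes, ftir_preprocess, cfg = ftir_cfg)
  segs <- kmeanspp_joint(pp, seg_cfg)

  # tissue shapes: moving = FTIR tissue mask (first section), fixed = target
  first <- pp[[1]]
  moving_mask <- binary_mask(first$grid,
                             matrix(first$tissue_mask, first$grid$n_rows,
                                    first$grid$n_cols, byrow = TRUE))
  if (is.null(fixed_mask)) {
    if (is.null(msi)) stop("guidance needs fixed_mask or msi to derive one")
    tic_img <- matrix(0, msi$grid$n_rows, msi$grid$n_cols)
    tic_img[cbind(msi$pixel_idx %/% msi$grid$n_cols + 1L,
                  msi$pixel_idx %% msi$grid$n_cols + 1L)] <-
      rowSums(msi$intensities)
    fixed_mask <- tissue_shape_mask(tic_img,
                                    pixel_size = msi$grid$pixel_size,
                                    origin = msi$grid$origin, seed = seed)
  }
  reg <- register(moving_mask, fixed_mask)

  if (is.null(target_idx)) {
    if (is.null(reference_mask)) {
      stop("either target_idx or reference_mask must be given")
    }
    dscs <- vapply(seq_len(seg_cfg$k), function(ix) {
      tm <- transfer_segment(segs[[1]], ix, reg$transform,
                             reference_mask$grid)
      dice(tm, reference_mask)
    }, numeric(1))
    target_idx <- which.max(dscs)
  }

  roi <- transfer_segment(segs[[1]], target_idx, reg$transform,
                          fixed_mask$grid)

  result <- list(
    segments = segs, registration = reg, target_idx = target_idx,
    roi = roi, fixed_mask = fixed_mask
  )

  if (mode == "interpretation") {
    stopifnot(inherits(msi, "msi_dataset"))
    binned <- msi_preprocess(msi, msi_cfg)
    split_ds <- extract_segment_spectra(binned, roi)
    lab <- c(rep(TRUE, length(split_ds$inside$pixel_idx)),
             rep(FALSE, length(split_ds$outside$pixel_idx)))
    result$binned <- binned
    result$features <- rank_features(
      rbind(split_ds$inside$intensities, split_ds$outside$intensities),
      binned$mz_axis, lab, criterion = "roc", segment_id = target_idx
    )
  } else {
    plan <- make_plan(roi, fixed_mask, time_per_pixel, data_per_pixel)
    result$plan <- plan
    result$report <- reduction_report(plan)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(segs)) {
      write_segment_map(segs[[nm]], file.path(out_dir,
                                              paste0("segments_", nm, ".csv")))
      write_segment_map(segs[[nm]], file.path(out_dir,
                                              paste0("segments_", nm, ".png")))
    }
    write_transform(reg$transform, file.path(out_dir, "transform.json"))
    write_mask(roi, file.path(out_dir, "roi_mask.png"))
    write_mask(roi, file.path(out_dir, "roi_mask.csv"))
    if (!is.null(result$features)) {
      write_feature_table(result$features,
                          file.path(out_dir, "features.csv"))
    }
    if (!is.null(result$plan)) {
      export_roi(result$plan, file.path(out_dir, "roi.json"))
      jsonlite::write_json(as.list(result$report),
                           file.path(out_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    manifest <- list(
      package = "ftirguide",
      version = as.character(utils::packageVersion("ftirguide")),
      mode = mode, k = seg_cfg$k, seed = seed, target_idx = target_idx,
      n_sections = length(cubes),
      section_ids = vapply(cubes, function(x) x$section_id, ""),
      ftir_cfg = unclass(ftir_cfg), seg_cfg = unclass(seg_cfg),
      msi_cfg = unclass(msi_cfg),
      registration = list(mse = reg$mse, dsc = reg$dsc,
                          converged = reg$converged)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    result$manifest_path <- file.path(out_dir, "manifest.json")
  }
  result
}
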