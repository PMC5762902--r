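#' Read an FTIR hyperspectral cube
#'
#' Two neutral carrier formats are supported: an ENVI-style header + flat
#' binary pair (`format = "envi"`, band-sequential, 64-bit little-endian) and
#' a plain CSV (`format = "csv"`) with columns `row, col, <wn1>, <wn2>, ...`
#' where the column names after the first two are wavenumbers in cm^-1.
#' An ascending wavenumber axis is reversed to the descending FTIR convention
#' (with the data reordered consistently); the flip is recorded in the
#' returned object's `axis_flipped` attribute.
#'
#' @param path File path (`.hdr` or the binary for ENVI, `.csv` for CSV).
#' @param format `"envi"`, `"csv"`, or `"auto"` (by extension).
#' @param pixel_size,origin Grid geometry fallbacks for files that do not
#'   carry them.
#' @return A [hyper_cube()].
#' @export
read_cube <- function(path, format = c("auto", "envi", "csv"),
                      pixel_size = NULL, origin = c(0, 0)) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "envi"
  }
  if (format == "csv") read_cube_csv(path, pixel_size %||% 1, origin)
  else read_cube_envi(path, pixel_size, origin)
}

read_cube_csv <- function(path, pixel_size, origin) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("row", "col") %in% names(df)[1:2])) {
    stop("CSV cube must start with columns row, col")
  }
  wn <- as.numeric(names(df)[-(1:2)])
  if (any(is.na(wn))) stop("CSV cube header must carry numeric wavenumbers")
  n_rows <- max(df$row) + 1L
  n_cols <- max(df$col) + 1L
  if (nrow(df) != n_rows * n_cols) stop("CSV cube must list every pixel")
  grid <- pixel_grid(n_rows, n_cols, pixel_size, origin)
  ord <- order(df$row * n_cols + df$col)
  data <- as.matrix(df[ord, -(1:2), drop = FALSE])
  dimnames(data) <- NULL
  flipped <- length(wn) >= 2 && wn[2] > wn[1]
  cube <- hyper_cube(grid, wn, data)
  attr(cube, "axis_flipped") <- flipped
  cube
}

read_cube_envi <- function(path, pixel_size, origin) {
  hdr <- if (grepl("\\.hdr$", path)) path else paste0(path, ".hdr")
  bin <- sub("\\.hdr$", "", hdr)
  if (!file.exists(hdr)) stop("missing ENVI header: ", hdr)
  lines <- readLines(hdr, warn = FALSE)
  txt <- paste(lines, collapse = "\n")
  field <- function(name) {
    m <- regmatches(txt, regexpr(
      sprintf("(?mi)^%s\\s*=\\s*([^\\{\\n]+)$", name), txt, perl = TRUE
    ))
    if (!length(m)) return(NA_character_)
    trimws(sub(sprintf("(?i)^%s\\s*=\\s*", name), "", m, perl = TRUE))
  }
  brace_field <- function(name) {
    m <- regmatches(txt, regexpr(
      sprintf("(?si)%s\\s*=\\s*\\{([^}]*)\\}", name), txt, perl = TRUE
    ))
    if (!length(m)) return(numeric(0))
    as.numeric(strsplit(gsub(sprintf("(?si)%s\\s*=\\s*\\{|\\}", name), "",
                             m, perl = TRUE), ",")[[1]])
  }
  samples <- as.integer(field("samples"))
  n_lines <- as.integer(field("lines"))
  bands <- as.integer(field("bands"))
  interleave <- tolower(field("interleave"))
  if (!identical(interleave, "bsq")) stop("only bsq interleave is supported")
  wn <- brace_field("wavelength")
  if (length(wn) != bands) {
    stop(sprintf("wavelength axis length (%d) != band count (%d)",
                 length(wn), bands))
  }
  ps <- suppressWarnings(as.numeric(field("pixel size")))
  if (is.na(ps)) ps <- pixel_size %||% 1
  org <- brace_field("origin")
  if (length(org) != 2) org <- origin

  n <- samples * n_lines * bands
  con <- file(bin, "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = n, size = 8, endian = "little")
  if (length(vals) != n) stop("ENVI binary shorter than header promises")
  # bsq: band-major, within a band pixels are row-major
  data <- matrix(vals, nrow = samples * n_lines, ncol = bands)
  grid <- pixel_grid(n_lines, samples, ps, org)
  flipped <- length(wn) >= 2 && wn[2] > wn[1]
  cube <- hyper_cube(grid, wn, data)
  attr(cube, "axis_flipped") <- flipped
  cube
}

#' Write an FTIR hyperspectral cube
#'
#' Counterpart of [read_cube()]; `read_cube(write_cube(cube, path))` is an
#' identity on grid, axis and absorbance values.
#'
#' @param cube A [hyper_cube()].
#' @param path Output path (`.csv`, or the ENVI binary path whose header will
#'   be `<path>.hdr`).
#' @param format `"auto"`, `"envi"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, format = c("auto", "envi", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "envi"
  }
  if (format == "csv") {
    ctr <- grid_centers(cube$grid)
    df <- data.frame(row = ctr$row, col = ctr$col, check.names = FALSE)
    df <- cbind(df, as.data.frame(cube$data))
    names(df)[-(1:2)] <- format(cube$wavenumbers, trim = TRUE, digits = 12)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    hdr <- paste0(path, ".hdr")
    g <- cube$grid
    writeLines(c(
      "ENVI",
      sprintf("samples = %d", g$n_cols),
      sprintf("lines = %d", g$n_rows),
      sprintf("bands = %d", length(cube$wavenumbers)),
      "header offset = 0",
      "file type = ENVI Standard",
      "data type = 5",
      "interleave = bsq",
      "byte order = 0",
      sprintf("pixel size = %.10g", g$pixel_size),
      sprintf("origin = {%.10g, %.10g}", g$origin[1], g$origin[2]),
      sprintf("wavelength = {%s}",
              paste(format(cube$wavenumbers, trim = TRUE, digits = 12),
                    collapse = ", "))
    ), hdr)
    con <- file(path, "wb")
    writeBin(as.numeric(cube$data), con, size = 8, endian = "little")
    close(con)
  }
  invisible(path)
}
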