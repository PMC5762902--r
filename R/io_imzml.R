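#' Read an imzML 1.1 mass spectrometry imaging file
#'
#' Reads the `.imzML` XML index and its binary `.ibd` companion into an
#' [msi_dataset()]. Both continuous (shared m/z axis) and processed
#' (per-pixel centroid) files are supported. imzML coordinates are 1-based;
#' they are shifted to the package's 0-based grid on read (and back on write).
#' A pixel missing from the file stays unpopulated — it is reported absent,
#' never zero-filled.
#'
#' @param path Path to the `.imzML` file; the `.ibd` is expected next to it.
#' @param pixel_size Fallback pixel size in micrometers, used only when the
#'   file declares none.
#' @return An [msi_dataset()].
#' @export
read_imzml <- function(path, pixel_size = NULL) {
  ibd <- ibd_path(path)
  if (!file.exists(ibd)) stop("missing .ibd file: ", ibd)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)

  mode_node <- xml2::xml_find_first(
    doc, "//fileContent/cvParam[@accession='IMS:1000030']"
  )
  mode <- if (!inherits(mode_node, "xml_missing")) "continuous" else {
    pn <- xml2::xml_find_first(
      doc, "//fileContent/cvParam[@accession='IMS:1000031']"
    )
    if (inherits(pn, "xml_missing")) stop("file declares neither continuous nor processed mode")
    "processed"
  }

  pol <- "positive"
  if (!inherits(xml2::xml_find_first(
    doc, "//cvParam[@accession='MS:1000129']"
  ), "xml_missing")) pol <- "negative"

  cv_num <- function(xpath) {
    n <- xml2::xml_find_first(doc, xpath)
    if (inherits(n, "xml_missing")) NA_real_
    else as.numeric(xml2::xml_attr(n, "value"))
  }
  nx <- cv_num("//scanSettings//cvParam[@accession='IMS:1000042']")
  ny <- cv_num("//scanSettings//cvParam[@accession='IMS:1000043']")
  psx <- cv_num("//scanSettings//cvParam[@accession='IMS:1000046']")
  psy <- cv_num("//scanSettings//cvParam[@accession='IMS:1000047']")
  if (is.na(psx)) psx <- psy
  if (is.na(psx)) {
    if (is.null(pixel_size)) stop("file declares no pixel size; pass pixel_size =")
    psx <- pixel_size
  } else if (!is.na(psy) && abs(psx - psy) > 1e-9 * psx) {
    stop("non-square pixels are not supported (pixel size x != y)")
  }

  # per-array precision from the referenceable param groups
  prec <- function(group_id) {
    g <- xml2::xml_find_first(doc, sprintf(
      "//referenceableParamGroup[@id='%s']", group_id
    ))
    if (inherits(g, "xml_missing")) return(8L)
    if (!inherits(xml2::xml_find_first(
      g, "./cvParam[@accession='MS:1000521']"
    ), "xml_missing")) 4L else 8L
  }
  sz_mz <- prec("mzArray")
  sz_int <- prec("intensityArray")

  spectra <- xml2::xml_find_all(doc, "//spectrum")
  ns <- length(spectra)
  if (ns == 0) stop("no spectra in file")

  xs <- ys <- integer(ns)
  mz_off <- mz_len <- int_off <- int_len <- numeric(ns)
  for (i in seq_len(ns)) {
    sp <- spectra[[i]]
    xs[i] <- as.integer(xml2::xml_attr(xml2::xml_find_first(
      sp, ".//cvParam[@accession='IMS:1000050']"
    ), "value"))
    ys[i] <- as.integer(xml2::xml_attr(xml2::xml_find_first(
      sp, ".//cvParam[@accession='IMS:1000051']"
    ), "value"))
    for (bda in xml2::xml_find_all(sp, ".//binaryDataArray")) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(bda, "./referenceableParamGroupRef"), "ref"
      )
      off <- as.numeric(xml2::xml_attr(xml2::xml_find_first(
        bda, "./cvParam[@accession='IMS:1000102']"
      ), "value"))
      len <- as.numeric(xml2::xml_attr(xml2::xml_find_first(
        bda, "./cvParam[@accession='IMS:1000103']"
      ), "value"))
      if (identical(ref, "mzArray")) {
        mz_off[i] <- off; mz_len[i] <- len
      } else {
        int_off[i] <- off; int_len[i] <- len
      }
    }
  }

  n_cols <- if (!is.na(nx)) as.integer(nx) else max(xs)
  n_rows <- if (!is.na(ny)) as.integer(ny) else max(ys)
  grid <- pixel_grid(n_rows, n_cols, psx)
  pixel_idx <- (ys - 1L) * n_cols + (xs - 1L)

  con <- file(ibd, "rb")
  on.exit(close(con))
  read_arr <- function(off, len, size) {
    seek(con, where = off, origin = "start")
    readBin(con, "double", n = len, size = size, endian = "little")
  }

  if (mode == "continuous") {
    mz_axis <- read_arr(mz_off[1], mz_len[1], sz_mz)
    ints <- matrix(0, ns, length(mz_axis))
    for (i in seq_len(ns)) ints[i, ] <- read_arr(int_off[i], int_len[i], sz_int)
    msi_dataset(grid, pixel_idx, mode = "continuous", mz_axis = mz_axis,
                intensities = ints, polarity = pol)
  } else {
    pk <- vector("list", ns)
    for (i in seq_len(ns)) {
      pk[[i]] <- data.frame(
        mz = read_arr(mz_off[i], mz_len[i], sz_mz),
        intensity = read_arr(int_off[i], int_len[i], sz_int)
      )
    }
    msi_dataset(grid, pixel_idx, mode = "processed", peaks = pk, polarity = pol)
  }
}

ibd_path <- function(path) sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)

#' Write an imzML 1.1 file pair
#'
#' Writes `ds` as `.imzML` + `.ibd` with 64-bit little-endian arrays, so
#' `read_imzml(write_imzml(ds, path))` is an identity on spectra and
#' coordinates. Internal 0-based coordinates are shifted to imzML's 1-based
#' convention on the way out.
#'
#' @param ds An [msi_dataset()].
#' @param path Output `.imzML` path (the `.ibd` is written next to it).
#' @return `path`, invisibly.
#' @export
write_imzml <- function(ds, path) {
  stopifnot(inherits(ds, "msi_dataset"))
  ibd <- ibd_path(path)
  uuid <- imzml_uuid()

  con <- file(ibd, "wb")
  writeBin(uuid$raw, con)
  offset <- 16
  offs <- list()
  put <- function(x) {
    writeBin(as.numeric(x), con, size = 8, endian = "little")
    o <- offset
    offset <<- offset + 8 * length(x)
    c(offset = o, length = length(x), bytes = 8 * length(x))
  }

  ns <- length(ds$pixel_idx)
  if (ds$mode == "continuous") {
    mz_rec <- put(ds$mz_axis)
    int_recs <- vector("list", ns)
    for (i in seq_len(ns)) int_recs[[i]] <- put(ds$intensities[i, ])
    mz_recs <- rep(list(mz_rec), ns)
  } else {
    mz_recs <- int_recs <- vector("list", ns)
    for (i in seq_len(ns)) {
      mz_recs[[i]] <- put(ds$peaks[[i]]$mz)
      int_recs[[i]] <- put(ds$peaks[[i]]$intensity)
    }
  }
  close(con)

  xr <- ds$pixel_idx %% ds$grid$n_cols + 1L
  yr <- ds$pixel_idx %/% ds$grid$n_cols + 1L
  mode_cv <- if (ds$mode == "continuous") {
    '<cvParam cvRef="IMS" accession="IMS:1000030" name="continuous" value=""/>'
  } else {
    '<cvParam cvRef="IMS" accession="IMS:1000031" name="processed" value=""/>'
  }
  pol_cv <- if (ds$polarity == "positive") {
    '<cvParam cvRef="MS" accession="MS:1000130" name="positive scan" value=""/>'
  } else {
    '<cvParam cvRef="MS" accession="MS:1000129" name="negative scan" value=""/>'
  }

  spec_xml <- character(ns)
  for (i in seq_len(ns)) {
    m <- mz_recs[[i]]; it <- int_recs[[i]]
    spec_xml[i] <- sprintf(
      '   <spectrum id="spectrum=%d" defaultArrayLength="%d" index="%d">
    <scanList count="1">
     <scan>
      <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>
      <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>
     </scan>
    </scanList>
    <binaryDataArrayList count="2">
     <binaryDataArray encodedLength="0">
      <referenceableParamGroupRef ref="mzArray"/>
      <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>
      <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%.0f"/>
      <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%.0f"/>
      <binary/>
     </binaryDataArray>
     <binaryDataArray encodedLength="0">
      <referenceableParamGroupRef ref="intensityArray"/>
      <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>
      <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%.0f"/>
      <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%.0f"/>
      <binary/>
     </binaryDataArray>
    </binaryDataArrayList>
   </spectrum>',
      i, it[["length"]], i - 1L, xr[i], yr[i],
      m[["offset"]], m[["length"]], m[["bytes"]],
      it[["offset"]], it[["length"]], it[["bytes"]]
    )
  }

  xml <- sprintf(
    '<?xml version="1.0" encoding="ISO-8859-1"?>
<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">
 <cvList count="3">
  <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="http://psidev.info/ms/mzML/psi-ms.obo"/>
  <cv id="UO" fullName="Unit Ontology" URI="http://obo.cvs.sourceforge.net/obo/obo/ontology/phenotype/unit.obo"/>
  <cv id="IMS" fullName="Imaging MS Ontology" URI="http://www.maldi-msi.org/download/imzml/imagingMS.obo"/>
 </cvList>
 <fileDescription>
  <fileContent>
   %s
   <cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="{%s}"/>
  </fileContent>
 </fileDescription>
 <referenceableParamGroupList count="2">
  <referenceableParamGroup id="mzArray">
   <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>
   <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>
   <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>
   <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>
  </referenceableParamGroup>
  <referenceableParamGroup id="intensityArray">
   <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>
   <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>
   <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>
   <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>
  </referenceableParamGroup>
 </referenceableParamGroupList>
 <softwareList count="1">
  <software id="ftirguide" version="0.1.0"/>
 </softwareList>
 <scanSettingsList count="1">
  <scanSettings id="scanSettings1">
   <cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/>
   <cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/>
   <cvParam cvRef="IMS" accession="IMS:1000046" name="pixel size x" value="%g" unitCvRef="UO" unitAccession="UO:0000017" unitName="micrometer"/>
   <cvParam cvRef="IMS" accession="IMS:1000047" name="pixel size y" value="%g" unitCvRef="UO" unitAccession="UO:0000017" unitName="micrometer"/>
  </scanSettings>
 </scanSettingsList>
 <instrumentConfigurationList count="1">
  <instrumentConfiguration id="IC1"/>
 </instrumentConfigurationList>
 <dataProcessingList count="1">
  <dataProcessing id="export">
   <processingMethod order="1" softwareRef="ftirguide">
    <cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>
   </processingMethod>
  </dataProcessing>
 </dataProcessingList>
 <run id="run1" defaultInstrumentConfigurationRef="IC1">
  <spectrumList count="%d" defaultDataProcessingRef="export">
%s
  </spectrumList>
 </run>
</mzML>
',
    mode_cv, uuid$string, ds$grid$n_cols, ds$grid$n_rows,
    ds$grid$pixel_size, ds$grid$pixel_size, ns,
    paste0(paste(spec_xml, collapse = "\n"),
           if (length(spec_xml)) "" else "")
  )
  # polarity is recorded per run via the first spectrum's scan settings; keep
  # it simple and file-level: append into fileContent
  xml <- sub("</fileContent>", paste0("  ", pol_cv, "\n  </fileContent>"), xml)
  writeLines(xml, path)
  invisible(path)
}

# 16 random-looking but RNG-state-free bytes (time + pid + counter hash)
imzml_uuid <- function() {
  env <- .ftirguide_state
  env$uuid_counter <- (env$uuid_counter %||% 0L) + 1L
  seedtxt <- paste(Sys.time(), Sys.getpid(), env$uuid_counter)
  h <- as.numeric(as.integer(charToRaw(seedtxt)))
  bytes <- integer(16)
  acc <- 5381
  for (i in seq_along(h)) acc <- (acc * 33 + h[i]) %% 2147483647
  for (i in 1:16) {
    acc <- (acc * 48271) %% 2147483647 # Lehmer step, stays below 2^53
    bytes[i] <- as.integer(acc %% 256)
  }
  raw <- as.raw(bytes)
  s <- paste(sprintf("%02X", bytes), collapse = "")
  structure(list(
    raw = raw,
    string = paste(substr(s, 1, 8), substr(s, 9, 12), substr(s, 13, 16),
                   substr(s, 17, 20), substr(s, 21, 32), sep = "-")
  ))
}

.ftirguide_state <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a
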