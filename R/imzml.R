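# imzML (processed mode) reader/writer. The imzML standard stores spectrum
# metadata in an mzML-dialect XML file and the m/z + intensity arrays in a
# binary companion ".ibd" whose first 16 bytes are the UUID echoed in the XML.
# Only processed mode (per-pixel m/z arrays, centroided peaks) is supported:
# the recalibration method operates on per-pixel centroids.

.ims_cv <- c(
  processed = "IMS:1000031", continuous = "IMS:1000030",
  uuid = "IMS:1000080",
  pos_x = "IMS:1000050", pos_y = "IMS:1000051",
  max_x = "IMS:1000042", max_y = "IMS:1000043",
  ext_offset = "IMS:1000102", ext_len = "IMS:1000103", ext_enc_len = "IMS:1000104"
)

.random_uuid_bytes <- function() {
  as.raw(sample.int(256L, 16L, replace = TRUE) - 1L)
}

.uuid_string <- function(bytes) {
  h <- format(bytes)
  paste0(
    paste(h[1:4], collapse = ""), "-", paste(h[5:6], collapse = ""), "-",
    paste(h[7:8], collapse = ""), "-", paste(h[9:10], collapse = ""), "-",
    paste(h[11:16], collapse = "")
  )
}

#' Write an MSI dataset to imzML (processed mode)
#'
#' Writes `<path>.imzML` and its binary companion `<path>.ibd`. m/z values are
#' stored as 64-bit floats (mass accuracy is the whole point) and intensities
#' as 32-bit floats.
#'
#' @param dataset An [msi_dataset()].
#' @param path Output path; an `.imzML` extension is added if absent, and the
#'   `.ibd` companion is placed alongside.
#' @return Invisibly, the path of the written `.imzML` file.
#' @export
write_imzml <- function(dataset, path) {
  stopifnot(inherits(dataset, "msi_dataset"))
  path <- sub("\\.imzML$", "", path, ignore.case = TRUE)
  xml_path <- paste0(path, ".imzML")
  ibd_path <- paste0(path, ".ibd")

  uuid <- .random_uuid_bytes()
  con <- file(ibd_path, open = "wb")
  ok <- FALSE
  on.exit(if (!ok) unlink(c(xml_path, ibd_path)))
  writeBin(uuid, con)
  offset <- 16L

  idx <- dataset$coords$pixel_index
  spectra_peaks <- split(
    dataset$peaks[c("mz", "intensity")],
    factor(dataset$peaks$pixel_index, levels = idx)
  )
  n <- length(idx)
  mz_off <- mz_len <- int_off <- int_len <- numeric(n)
  for (i in seq_len(n)) {
    sp <- spectra_peaks[[i]]
    mz_off[i] <- offset
    mz_len[i] <- nrow(sp)
    if (nrow(sp) > 0) writeBin(as.double(sp$mz), con, size = 8, endian = "little")
    offset <- offset + 8 * nrow(sp)
    int_off[i] <- offset
    int_len[i] <- nrow(sp)
    if (nrow(sp) > 0) writeBin(as.double(sp$intensity), con, size = 4, endian = "little")
    offset <- offset + 4 * nrow(sp)
  }
  close(con)

  pol_acc <- if (dataset$polarity == "negative") "MS:1000129" else "MS:1000130"
  pol_name <- if (dataset$polarity == "negative") "negative scan" else "positive scan"

  cv <- function(acc, name, value = NULL) {
    ref <- if (startsWith(acc, "IMS")) "IMS" else "MS"
    v <- if (is.null(value)) "" else sprintf(' value="%s"', value)
    sprintf('<cvParam cvRef="%s" accession="%s" name="%s"%s/>', ref, acc, name, v)
  }

  spec_xml <- character(n)
  for (i in seq_len(n)) {
    spec_xml[i] <- sprintf(
      paste0(
        '<spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">',
        '%s',
        '<scanList count="1"><scan>%s%s</scan></scanList>',
        '<binaryDataArrayList count="2">',
        '<binaryDataArray encodedLength="0"><referenceableParamGroupRef ref="mzArray"/>%s%s%s<binary/></binaryDataArray>',
        '<binaryDataArray encodedLength="0"><referenceableParamGroupRef ref="intensityArray"/>%s%s%s<binary/></binaryDataArray>',
        '</binaryDataArrayList></spectrum>'
      ),
      i - 1L, i, mz_len[i],
      cv(pol_acc, pol_name),
      cv(.ims_cv[["pos_x"]], "position x", dataset$coords$x[i]),
      cv(.ims_cv[["pos_y"]], "position y", dataset$coords$y[i]),
      cv(.ims_cv[["ext_offset"]], "external offset", format(mz_off[i], scientific = FALSE)),
      cv(.ims_cv[["ext_len"]], "external array length", mz_len[i]),
      cv(.ims_cv[["ext_enc_len"]], "external encoded length", 8 * mz_len[i]),
      cv(.ims_cv[["ext_offset"]], "external offset", format(int_off[i], scientific = FALSE)),
      cv(.ims_cv[["ext_len"]], "external array length", int_len[i]),
      cv(.ims_cv[["ext_enc_len"]], "external encoded length", 4 * int_len[i])
    )
  }

  doc <- sprintf(
    paste0(
      '<?xml version="1.0" encoding="UTF-8"?>\n',
      '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
      '<cvList count="2">',
      '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="http://psidev.info/ms/mzML/psi-ms.obo"/>',
      '<cv id="IMS" fullName="Imaging MS Ontology" URI="http://www.maldi-msi.org/download/imzml/imagingMS.obo"/>',
      '</cvList>',
      '<fileDescription><fileContent>',
      '%s%s%s',
      '<userParam name="analyzer" value="%s"/>',
      '</fileContent></fileDescription>',
      '<referenceableParamGroupList count="2">',
      '<referenceableParamGroup id="mzArray">%s%s%s%s</referenceableParamGroup>',
      '<referenceableParamGroup id="intensityArray">%s%s%s%s</referenceableParamGroup>',
      '</referenceableParamGroupList>',
      '<softwareList count="1"><software id="msirecal" version="0.1.0"/></softwareList>',
      '<scanSettingsList count="1"><scanSettings id="scansettings1">%s%s</scanSettings></scanSettingsList>',
      '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC1"/></instrumentConfigurationList>',
      '<dataProcessingList count="1"><dataProcessing id="export"><processingMethod order="1" softwareRef="msirecal"/></dataProcessing></dataProcessingList>',
      '<run id="run1" defaultInstrumentConfigurationRef="IC1">',
      '<spectrumList count="%d" defaultDataProcessingRef="export">%s</spectrumList>',
      '</run></mzML>'
    ),
    cv("MS:1000127", "centroid spectrum"),
    cv(.ims_cv[["processed"]], "processed"),
    cv(.ims_cv[["uuid"]], "universally unique identifier",
       paste0("{", .uuid_string(uuid), "}")),
    dataset$analyzer,
    cv("MS:1000514", "m/z array"), cv("MS:1000523", "64-bit float"),
    cv("MS:1000576", "no compression"), cv("IMS:1000101", "external data", "true"),
    cv("MS:1000515", "intensity array"), cv("MS:1000521", "32-bit float"),
    cv("MS:1000576", "no compression"), cv("IMS:1000101", "external data", "true"),
    cv(.ims_cv[["max_x"]], "max count of pixels x", dataset$n_cols),
    cv(.ims_cv[["max_y"]], "max count of pixels y", dataset$n_rows),
    n, paste(spec_xml, collapse = "")
  )
  writeLines(doc, xml_path, useBytes = TRUE)
  ok <- TRUE
  invisible(xml_path)
}

.cv_value <- function(node, accession, xpath = ".//d1:cvParam") {
  p <- xml2::xml_find_first(
    node, sprintf("%s[@accession='%s']", xpath, accession)
  )
  if (inherits(p, "xml_missing")) NA_character_ else xml2::xml_attr(p, "value")
}

.has_cv <- function(node, accession) {
  !inherits(
    xml2::xml_find_first(node, sprintf(".//d1:cvParam[@accession='%s']", accession)),
    "xml_missing"
  )
}

#' Read a processed-mode imzML file
#'
#' Spectra are returned in file storage order and `pixel_index` is assigned
#' `0..N-1` in that order: storage order is taken as acquisition order, the
#' time proxy used by the drift models. Masses are sorted ascending per pixel
#' (intensities permuted along) if the file stores them unsorted.
#'
#' @param path Path to the `.imzML` file; the `.ibd` companion must sit next
#'   to it.
#' @param analyzer Optional override of the analyzer type when the file does
#'   not record one (`"orbitrap"` or `"tof"`).
#' @param pixel_order Optional integer permutation of `seq_len(N)` giving the
#'   true acquisition order of the stored spectra, for files whose storage
#'   order is not the acquisition order.
#' @return An [msi_dataset()].
#' @export
read_imzml <- function(path, analyzer = NULL, pixel_order = NULL) {
  if (!file.exists(path)) stop("imzML file not found: ", path, call. = FALSE)
  ibd_path <- paste0(sub("\\.imzML$", "", path, ignore.case = TRUE), ".ibd")
  if (!file.exists(ibd_path)) {
    stop("missing ibd companion file: ", ibd_path, call. = FALSE)
  }
  doc <- xml2::read_xml(path)

  if (.has_cv(doc, .ims_cv[["continuous"]]) && !.has_cv(doc, .ims_cv[["processed"]])) {
    stop("continuous-mode imzML is not supported; convert the file to ",
         "processed mode (per-pixel centroid m/z arrays) first", call. = FALSE)
  }

  # resolve array dtypes from the referenceable param groups
  groups <- xml2::xml_find_all(doc, ".//d1:referenceableParamGroup")
  dtype_of <- function(g) {
    if (.has_cv(g, "MS:1000523")) list(size = 8) else
      if (.has_cv(g, "MS:1000521")) list(size = 4) else
        stop("unsupported binary data type (only 32/64-bit float)", call. = FALSE)
  }
  group_info <- stats::setNames(
    lapply(groups, function(g) {
      list(is_mz = .has_cv(g, "MS:1000514"), size = dtype_of(g)$size)
    }),
    xml2::xml_attr(groups, "id")
  )

  file_analyzer <- {
    up <- xml2::xml_find_first(doc, ".//d1:userParam[@name='analyzer']")
    if (inherits(up, "xml_missing")) NA_character_ else xml2::xml_attr(up, "value")
  }
  analyzer <- analyzer %||% (if (file_analyzer %in% c("orbitrap", "tof")) file_analyzer else "orbitrap")

  spectra <- xml2::xml_find_all(doc, ".//d1:spectrum")
  n <- length(spectra)
  if (n == 0) stop("no spectra found in ", path, call. = FALSE)

  polarity <- if (.has_cv(spectra[[1]], "MS:1000129")) "negative" else "positive"

  ibd_size <- file.info(ibd_path)$size
  con <- file(ibd_path, open = "rb")
  on.exit(close(con))

  read_array <- function(bda) {
    ref <- xml2::xml_attr(
      xml2::xml_find_first(bda, "./d1:referenceableParamGroupRef"), "ref"
    )
    info <- group_info[[ref]]
    off <- as.numeric(.cv_value(bda, .ims_cv[["ext_offset"]]))
    len <- as.integer(.cv_value(bda, .ims_cv[["ext_len"]]))
    if (is.na(off) || is.na(len)) {
      stop("garbled imzML: missing external offset/length in ", path, call. = FALSE)
    }
    if (off + info$size * len > ibd_size) {
      stop("garbled ibd companion ", ibd_path,
           ": array extends past end of file", call. = FALSE)
    }
    seek(con, where = off, origin = "start")
    vals <- readBin(con, "double", n = len, size = info$size, endian = "little")
    list(is_mz = info$is_mz, values = vals)
  }

  peak_list <- vector("list", n)
  x <- integer(n); y <- integer(n)
  for (i in seq_len(n)) {
    sp <- spectra[[i]]
    x[i] <- as.integer(.cv_value(sp, .ims_cv[["pos_x"]]))
    y[i] <- as.integer(.cv_value(sp, .ims_cv[["pos_y"]]))
    bdas <- xml2::xml_find_all(sp, ".//d1:binaryDataArray")
    arrays <- lapply(bdas, read_array)
    mz <- intensity <- numeric(0)
    for (a in arrays) {
      if (a$is_mz) mz <- a$values else intensity <- a$values
    }
    if (length(mz) != length(intensity)) {
      stop("garbled spectrum ", i, ": m/z and intensity lengths differ", call. = FALSE)
    }
    if (is.unsorted(mz)) {
      ord <- order(mz)
      mz <- mz[ord]; intensity <- intensity[ord]
    }
    peak_list[[i]] <- tibble::tibble(mz = mz, intensity = intensity)
  }

  storage_to_acq <- if (is.null(pixel_order)) seq_len(n) else {
    stopifnot(length(pixel_order) == n, all(sort(pixel_order) == seq_len(n)))
    pixel_order
  }
  pix_idx <- storage_to_acq - 1L

  n_cols <- as.integer(.cv_value(doc, .ims_cv[["max_x"]]))
  n_rows <- as.integer(.cv_value(doc, .ims_cv[["max_y"]]))
  if (is.na(n_cols)) n_cols <- max(x)
  if (is.na(n_rows)) n_rows <- max(y)

  npk <- vapply(peak_list, nrow, 0L)
  peaks <- tibble::tibble(
    pixel_index = rep(pix_idx, npk),
    mz = unlist(lapply(peak_list, `[[`, "mz"), use.names = FALSE),
    intensity = unlist(lapply(peak_list, `[[`, "intensity"), use.names = FALSE)
  )
  if (nrow(peaks) == 0) {
    peaks <- tibble::tibble(pixel_index = integer(), mz = numeric(), intensity = numeric())
  }
  coords <- tibble::tibble(pixel_index = pix_idx, x = x, y = y)
  msi_dataset(peaks, coords, n_rows = n_rows, n_cols = n_cols,
              polarity = polarity, analyzer = analyzer)
}

#' Read a dense 0/1 ROI mask from CSV
#'
#' @param path CSV file with `n_rows` lines of `n_cols` comma-separated 0/1
#'   entries, row-major in image orientation (row = y, column = x).
#' @param n_rows,n_cols Expected dimensions.
#' @return An integer matrix of 0/1 values (`n_rows x n_cols`).
#' @export
read_roi_mask <- function(path, n_rows, n_cols) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != n_rows) {
    stop(sprintf("ROI mask has %d rows, expected %d", length(lines), n_rows),
         call. = FALSE)
  }
  rows <- lapply(seq_along(lines), function(r) {
    vals <- trimws(strsplit(lines[[r]], ",", fixed = TRUE)[[1]])
    if (length(vals) != n_cols) {
      stop(sprintf("ROI mask row %d has %d columns, expected %d",
                   r, length(vals), n_cols), call. = FALSE)
    }
    bad <- which(!vals %in% c("0", "1"))
    if (length(bad) > 0) {
      stop(sprintf("non-binary ROI mask entry '%s' at row %d, column %d",
                   vals[bad[1]], r, bad[1]), call. = FALSE)
    }
    as.integer(vals)
  })
  do.call(rbind, rows)
}

#' Write an ROI mask to CSV
#' @param roi 0/1 matrix.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_roi_mask <- function(roi, path) {
  utils::write.table(roi, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read user pixel labels for ROI training
#' @param path CSV with header `x,y,label`, label in `{sample, background}`.
#' @return Tibble with columns `x`, `y`, `label`.
#' @export
read_pixel_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("x", "y", "label") %in% names(df)))
  if (!all(df$label %in% c("sample", "background"))) {
    stop("labels must be 'sample' or 'background'", call. = FALSE)
  }
  tibble::as_tibble(df[c("x", "y", "label")])
}
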