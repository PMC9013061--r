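#' Construct an MSI dataset
#'
#' An `msi_dataset` bundles the centroided peak lists of one mass spectrometry
#' imaging acquisition: one spectrum per pixel, each a list of (m/z, intensity)
#' centroids, together with the pixel grid geometry, the ionisation polarity
#' and the mass analyzer type. The pixel index is the acquisition order
#' (0-based) and acts as the proxy for acquisition time throughout the
#' recalibration workflow.
#'
#' @param peaks A data frame with columns `pixel_index` (integer, 0-based
#'   acquisition order), `mz` (numeric, Thomson) and `intensity` (numeric,
#'   non-negative). Peaks are sorted by pixel and ascending m/z on input.
#' @param coords A data frame with columns `pixel_index`, `x`, `y` (1-based
#'   grid coordinates, imzML convention), one row per pixel. Pixels with no
#'   peaks still need a row here.
#' @param n_rows,n_cols Grid dimensions (rows indexed by `y`, columns by `x`).
#' @param polarity `"positive"` or `"negative"`.
#' @param analyzer `"orbitrap"` or `"tof"`.
#'
#' @return An object of class `msi_dataset`: a list with tibbles `peaks` and
#'   `coords` plus the metadata fields above.
#' @export
msi_dataset <- function(peaks, coords, n_rows, n_cols,
                        polarity = c("negative", "positive"),
                        analyzer = c("orbitrap", "tof")) {
  polarity <- match.arg(polarity)
  analyzer <- match.arg(analyzer)
  peaks <- tibble::as_tibble(peaks)
  coords <- tibble::as_tibble(coords)
  stopifnot(
    all(c("pixel_index", "mz", "intensity") %in% names(peaks)),
    all(c("pixel_index", "x", "y") %in% names(coords))
  )
  if (anyDuplicated(coords$pixel_index)) {
    stop("pixel_index must be unique across pixels", call. = FALSE)
  }
  if (any(peaks$intensity < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  if (any(!peaks$pixel_index %in% coords$pixel_index)) {
    stop("peaks reference pixel_index values absent from coords", call. = FALSE)
  }
  if (any(coords$x < 1L) || any(coords$y < 1L) ||
      any(coords$x > n_cols) || any(coords$y > n_rows)) {
    stop("coordinates outside the ", n_rows, " x ", n_cols, " grid", call. = FALSE)
  }
  peaks <- dplyr::arrange(peaks, .data$pixel_index, .data$mz)
  coords <- dplyr::arrange(coords, .data$pixel_index)
  structure(
    list(
      peaks = peaks, coords = coords,
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      polarity = polarity, analyzer = analyzer
    ),
    class = "msi_dataset"
  )
}

#' Number of pixels in an MSI dataset
#' @param dataset An `msi_dataset`.
#' @return Integer pixel count.
#' @export
n_pixels <- function(dataset) nrow(dataset$coords)

#' @export
print.msi_dataset <- function(x, ...) {
  cat(sprintf(
    "<msi_dataset> %d pixels on a %d x %d grid | %s mode, %s analyzer | %d peaks\n",
    n_pixels(x), x$n_rows, x$n_cols, x$polarity, x$analyzer, nrow(x$peaks)
  ))
  invisible(x)
}

#' Extract one pixel's spectrum
#' @param dataset An `msi_dataset`.
#' @param pixel_index 0-based acquisition index.
#' @return Tibble with columns `mz`, `intensity`, sorted by m/z.
#' @export
pixel_spectrum <- function(dataset, pixel_index) {
  dplyr::filter(dataset$peaks, .data$pixel_index == !!pixel_index)[c("mz", "intensity")]
}

#' Map pixels of an ROI mask to acquisition indices
#'
#' @param dataset An `msi_dataset`.
#' @param roi A 0/1 matrix of dimension `n_rows x n_cols` (rows = y).
#' @return Integer vector of `pixel_index` values lying on the mask.
#' @export
roi_pixel_indices <- function(dataset, roi) {
  stopifnot(nrow(roi) == dataset$n_rows, ncol(roi) == dataset$n_cols)
  on_roi <- roi[cbind(dataset$coords$y, dataset$coords$x)] == 1
  sort(dataset$coords$pixel_index[on_roi])
}
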