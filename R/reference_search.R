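# Reference database expansion into adduct m/z values and ppm-window search
# of candidate reference peaks across ROI pixels.

# Singly-charged adduct mass shifts in Da (monoisotopic, electron-corrected).
.adducts <- tibble::tibble(
  label = c("[M+H]+", "[M+Na]+", "[M+K]+", "[M-H]-", "[M+Cl]-"),
  mass_delta = c(1.007276, 22.989218, 38.963158, -1.007276, 34.969402),
  polarity = c("positive", "positive", "positive", "negative", "negative")
)

#' Standard adduct table
#' @return Tibble with columns `label`, `mass_delta` (Da), `polarity`.
#' @export
adduct_table <- function() .adducts

#' Adduct m/z from a neutral monoisotopic mass
#'
#' @param neutral_mass Neutral monoisotopic mass in Da (> 0).
#' @param adduct Adduct label, one of `adduct_table()$label`.
#' @param polarity Optional dataset polarity; an adduct of the other polarity
#'   raises an error.
#' @return m/z of the singly charged adduct ion (Th).
#' @export
adduct_mz <- function(neutral_mass, adduct, polarity = NULL) {
  stopifnot(all(neutral_mass > 0))
  row <- .adducts[.adducts$label == adduct, ]
  if (nrow(row) == 0) stop("unknown adduct: ", adduct, call. = FALSE)
  if (!is.null(polarity) && row$polarity != polarity) {
    stop("adduct ", adduct, " does not match ", polarity, " polarity mode",
         call. = FALSE)
  }
  neutral_mass + row$mass_delta
}

#' Read a reference-ion database
#' @param path CSV with header `name,formula,neutral_mass,class`.
#' @return Tibble of database records.
#' @export
read_reference_db <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "formula", "neutral_mass", "class") %in% names(df)))
  if (any(df$neutral_mass <= 0)) stop("neutral masses must be positive", call. = FALSE)
  tibble::as_tibble(df)
}

#' Expand a neutral-mass database into candidate reference m/z values
#'
#' Applies every adduct of the dataset polarity to every database record and
#' deduplicates candidate m/z values identical to 1e-4 Th (contributing
#' molecules are concatenated in `name`).
#'
#' @param db Tibble from [read_reference_db()] (columns `name`,
#'   `neutral_mass`, ...).
#' @param polarity `"positive"` or `"negative"`.
#' @return Tibble with columns `mz`, `name`, `adduct`, sorted by m/z.
#' @export
expand_adducts <- function(db, polarity = c("negative", "positive")) {
  polarity <- match.arg(polarity)
  ad <- .adducts[.adducts$polarity == polarity, ]
  out <- tidyr::crossing(db, ad) |>
    dplyr::mutate(mz = .data$neutral_mass + .data$mass_delta) |>
    dplyr::group_by(key = round(.data$mz, 4)) |>
    dplyr::summarise(
      mz = .data$mz[1],
      name = paste(unique(.data$name), collapse = ";"),
      adduct = paste(unique(.data$label), collapse = ";"),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$mz)
  out[c("mz", "name", "adduct")]
}

#' Symmetric ppm search window around a mass
#'
#' The half-width is `lambda = W * M * 1e-6`, the absolute mass distance
#' corresponding to a relative error of `W` ppm; the window is closed on both
#' ends.
#'
#' @param mz Reference m/z (> 0).
#' @param ppm Window half-width in ppm (> 0 allowed; 0 gives the degenerate
#'   interval).
#' @return Numeric vector `c(lower, upper)`.
#' @export
ppm_window <- function(mz, ppm) {
  stopifnot(mz > 0, ppm >= 0)
  lambda <- ppm * mz * 1e-6
  c(mz - lambda, mz + lambda)
}

#' Search all ROI pixels for peaks matching a reference mass
#'
#' Finds every observed peak within the closed ppm window around `mz` in every
#' ROI pixel (multiple matches per pixel are kept). The lookup is a binary
#' search on the globally m/z-sorted peak table.
#'
#' @param dataset An [msi_dataset()].
#' @param roi 0/1 ROI matrix, or `NULL` to search all pixels.
#' @param mz Reference m/z (Th).
#' @param ppm Search window half-width in ppm.
#' @return Tibble with columns `pixel_index`, `peak_index` (1-based index into
#'   the pixel's m/z-sorted peak list), `mz_obs`, `intensity`, plus attributes
#'   `reference_mz` and `coverage` (fraction of ROI pixels with >= 1 match).
#' @export
search_reference <- function(dataset, roi, mz, ppm) {
  idx <- .peak_index(dataset)
  roi_pix <- if (is.null(roi)) dataset$coords$pixel_index else roi_pixel_indices(dataset, roi)
  n_roi <- length(roi_pix)
  win <- ppm_window(mz, ppm)
  lo <- findInterval(win[1], idx$mz_sorted, left.open = TRUE) + 1L
  hi <- findInterval(win[2], idx$mz_sorted)
  if (hi < lo || n_roi == 0) {
    out <- tibble::tibble(pixel_index = integer(), peak_index = integer(),
                          mz_obs = numeric(), intensity = numeric())
  } else {
    sel <- idx$order[lo:hi]
    keep <- dataset$peaks$pixel_index[sel] %in% roi_pix
    sel <- sel[keep]
    out <- tibble::tibble(
      pixel_index = dataset$peaks$pixel_index[sel],
      peak_index = idx$within_pixel_rank[sel],
      mz_obs = dataset$peaks$mz[sel],
      intensity = dataset$peaks$intensity[sel]
    ) |> dplyr::arrange(.data$pixel_index, .data$mz_obs)
  }
  attr(out, "reference_mz") <- mz
  attr(out, "coverage") <- if (n_roi == 0) 0 else
    length(unique(out$pixel_index)) / n_roi
  out
}

# Global sorted-m/z index over the peak table, cached on the dataset.
.peak_index <- function(dataset) {
  cached <- attr(dataset, "peak_index")
  if (!is.null(cached)) return(cached)
  ord <- order(dataset$peaks$mz)
  rank_within <- stats::ave(
    seq_len(nrow(dataset$peaks)), dataset$peaks$pixel_index,
    FUN = seq_along
  )
  list(order = ord, mz_sorted = dataset$peaks$mz[ord],
       within_pixel_rank = as.integer(rank_within))
}

#' Search many reference masses at once
#'
#' @inheritParams search_reference
#' @param mzs Vector of candidate reference m/z values.
#' @return Named list of match tables (names = formatted m/z), one per
#'   reference, each as returned by [search_reference()].
#' @export
search_references <- function(dataset, roi, mzs, ppm) {
  idx <- .peak_index(dataset)
  attr(dataset, "peak_index") <- idx
  stats::setNames(
    lapply(mzs, function(m) search_reference(dataset, roi, m, ppm)),
    format(mzs, nsmall = 4, trim = TRUE)
  )
}

#' Coverage filter over candidate reference match tables
#'
#' Keeps a candidate iff peaks matching it are found in at least `min_frac`
#' of the ROI pixels (distinct pixels; duplicate matches in one pixel count
#' once).
#'
#' @param tables List of match tables from [search_references()].
#' @param n_roi Number of ROI pixels (> 0).
#' @param min_frac Minimum covered fraction, default 0.75.
#' @return The filtered list (kept tables unchanged).
#' @export
coverage_filter <- function(tables, n_roi, min_frac = 0.75) {
  stopifnot(n_roi > 0)
  keep <- vapply(tables, function(t) {
    length(unique(t$pixel_index)) / n_roi >= min_frac
  }, logical(1))
  tables[keep]
}
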