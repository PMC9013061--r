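# Sample vs off-sample pixel classification: 1-m/z binned intensity features,
# a linear max-margin classifier trained on user-labeled pixels, and a
# connected-component cleanup of the predicted mask.

#' Bin spectra onto a uniform 1-m/z grid
#'
#' Each peak's intensity is added to the half-open bin `[k, k+1)` containing
#' its m/z; bins span `floor(min mz) .. ceiling(max mz)` over the whole
#' acquisition. Binning conserves each pixel's total intensity.
#'
#' @param dataset An [msi_dataset()].
#' @return A list with `matrix` (pixels x bins, rows in `pixel_index` order)
#'   and `bin_edges` (integer lower edges).
#' @export
bin_spectra <- function(dataset) {
  stopifnot(n_pixels(dataset) > 0)
  pk <- dataset$peaks
  if (nrow(pk) == 0) stop("dataset has no peaks to bin", call. = FALSE)
  lo <- floor(min(pk$mz)); hi <- ceiling(max(pk$mz))
  if (hi == max(pk$mz)) hi <- hi + 1  # peak exactly on the top edge
  edges <- lo:(hi - 1)
  nb <- length(edges)
  pix_levels <- dataset$coords$pixel_index
  i <- match(pk$pixel_index, pix_levels)
  j <- floor(pk$mz) - lo + 1
  m <- matrix(0, nrow = length(pix_levels), ncol = nb)
  acc <- rowsum(pk$intensity, group = (j - 1) * length(pix_levels) + i)
  idx <- as.integer(rownames(acc))
  m[idx] <- acc[, 1]
  list(matrix = m, bin_edges = edges, pixel_index = pix_levels)
}

#' Fit the linear SVM ROI classifier
#'
#' Rows are normalized to unit total intensity before fitting (empty pixels
#' stay zero), then a linear support vector machine separates the labeled
#' sample and background pixels.
#'
#' @param features Output of [bin_spectra()].
#' @param labels Tibble with `x`, `y`, `label` (see [read_pixel_labels()]).
#' @param dataset The [msi_dataset()] the features came from (for the
#'   coordinate lookup).
#' @param cost SVM regularization parameter C.
#' @return An object of class `roi_classifier`.
#' @export
fit_roi_classifier <- function(features, labels, dataset, cost = 1) {
  if (length(unique(labels$label)) < 2) {
    stop("need labeled pixels of both classes (sample and background)",
         call. = FALSE)
  }
  key <- paste(dataset$coords$x, dataset$coords$y)
  row_of <- match(paste(labels$x, labels$y), key)
  if (anyNA(row_of)) stop("label coordinates outside the pixel grid", call. = FALSE)
  m <- .normalize_rows(features$matrix)
  fit <- e1071::svm(
    x = m[row_of, , drop = FALSE],
    y = factor(labels$label, levels = c("background", "sample")),
    kernel = "linear", cost = cost, scale = FALSE
  )
  structure(list(svm = fit, bin_edges = features$bin_edges),
            class = "roi_classifier")
}

.normalize_rows <- function(m) {
  tot <- rowSums(m)
  tot[tot == 0] <- 1
  m / tot
}

#' Predict the ROI mask for all pixels
#'
#' @param classifier A fitted [fit_roi_classifier()] model.
#' @param features Output of [bin_spectra()].
#' @param dataset The corresponding [msi_dataset()].
#' @return A 0/1 integer matrix (`n_rows x n_cols`); pixels without a spectrum
#'   are 0.
#' @export
predict_roi <- function(classifier, features, dataset) {
  m <- .normalize_rows(features$matrix)
  pred <- predict(classifier$svm, m)
  roi <- matrix(0L, dataset$n_rows, dataset$n_cols)
  roi[cbind(dataset$coords$y, dataset$coords$x)] <- as.integer(pred == "sample")
  roi
}

#' Remove small 8-connected components from a binary mask
#'
#' Sample components (8-neighborhood connectivity, diagonals included) with
#' fewer than `min_size` pixels are reassigned to the background. The
#' operation is idempotent.
#'
#' @param mask 0/1 matrix.
#' @param min_size Components strictly smaller than this survive threshold are
#'   removed; defaults to 50 pixels.
#' @return The cleaned 0/1 matrix.
#' @export
clean_components <- function(mask, min_size = 50L) {
  lab <- label_components(mask)
  if (max(lab) == 0) return(mask)
  sizes <- tabulate(lab[lab > 0])
  drop <- which(sizes < min_size)
  out <- mask
  out[lab %in% drop] <- 0L
  out
}

#' Label 8-connected components of a binary mask
#'
#' @param mask 0/1 matrix.
#' @return Integer matrix of component labels (0 = background), numbered in
#'   raster-scan order of first encounter.
#' @export
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  offs <- cbind(
    dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
    dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  )
  for (start in which(mask == 1L & lab == 0L)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue) > 0) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((cur - 1L) %% nr) + 1L
      cc <- ((cur - 1L) %/% nr) + 1L
      nb_r <- r + offs[, 1]; nb_c <- cc + offs[, 2]
      ok <- nb_r >= 1L & nb_r <= nr & nb_c >= 1L & nb_c <= nc
      nb <- (nb_c[ok] - 1L) * nr + nb_r[ok]
      nb <- nb[mask[nb] == 1L & lab[nb] == 0L]
      lab[nb] <- nxt
      queue <- c(queue, nb)
    }
  }
  lab
}

#' Train and apply the full ROI selection stage
#'
#' Convenience wrapper: bin, fit the SVM on the labels, predict all pixels and
#' clean small components.
#'
#' @inheritParams fit_roi_classifier
#' @param min_size Connected-component size threshold (pixels).
#' @return A 0/1 ROI matrix.
#' @export
select_roi <- function(dataset, labels, cost = 1, min_size = 50L) {
  features <- bin_spectra(dataset)
  clf <- fit_roi_classifier(features, labels, dataset, cost = cost)
  clean_components(predict_roi(clf, features, dataset), min_size = min_size)
}
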