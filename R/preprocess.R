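# Optional TOF-style preprocessing: baseline-noise thresholding (kneedle knee
# detection on the sorted intensity curve), Savitzky-Golay smoothing and
# centroid detection. Public centroided datasets skip this stage entirely.

#' Preprocessing configuration
#'
#' @param sg_window Savitzky-Golay window length in points (odd).
#' @param sg_order Savitzky-Golay polynomial order, `< sg_window`.
#' @param min_peak_points Minimum number of contiguous above-threshold points
#'   supporting a centroid.
#' @param kneedle_sensitivity Minimum normalized chord distance for a knee to
#'   count as pronounced; below it the threshold falls back to the minimum
#'   intensity.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(sg_window = 7L, sg_order = 3L,
                              min_peak_points = 3L,
                              kneedle_sensitivity = 0.01) {
  stopifnot(sg_window %% 2 == 1, sg_window > sg_order, min_peak_points >= 3)
  structure(
    list(sg_window = as.integer(sg_window), sg_order = as.integer(sg_order),
         min_peak_points = as.integer(min_peak_points),
         kneedle_sensitivity = kneedle_sensitivity),
    class = "preprocess_config"
  )
}

#' Baseline-noise threshold by knee detection
#'
#' Sorts the intensities ascending, rescales the curve to the unit square and
#' returns the intensity at the point of maximum perpendicular distance to the
#' chord joining the curve's endpoints (the knee). Intensities below the
#' threshold are treated as baseline noise.
#'
#' @param intensities Non-negative numeric vector, length >= 10.
#' @param sensitivity Minimum normalized chord distance for a knee to be
#'   accepted; with no pronounced knee the minimum intensity is returned with
#'   a warning.
#' @return A single threshold value within `[min, max]` of the input.
#' @export
kneedle_threshold <- function(intensities, sensitivity = 0.01) {
  stopifnot(length(intensities) >= 10, all(intensities >= 0))
  y <- sort(intensities)
  n <- length(y)
  if (diff(range(y)) == 0) {
    warning("all intensities equal; threshold set to that value")
    return(y[1])
  }
  xs <- (seq_len(n) - 1) / (n - 1)
  ys <- (y - y[1]) / (y[n] - y[1])
  # perpendicular distance to the chord from (0,0) to (1,1): |x - y| / sqrt(2)
  d <- abs(xs - ys) / sqrt(2)
  if (max(d) < sensitivity) {
    warning("no pronounced knee in the intensity curve; using minimum intensity")
    return(y[1])
  }
  y[which.max(d)]
}

#' Savitzky-Golay smoothing of a spectrum
#'
#' Least-squares local-polynomial smoothing of the intensity track on its
#' ordered m/z axis. Reproduces polynomials up to `sg_order` exactly.
#'
#' @param spectrum Data frame with columns `mz`, `intensity`.
#' @param config A [preprocess_config()].
#' @return Tibble of the same length with smoothed intensities.
#' @export
smooth_spectrum <- function(spectrum, config = preprocess_config()) {
  n <- nrow(spectrum)
  if (config$sg_window > n) {
    stop("Savitzky-Golay window (", config$sg_window,
         ") longer than spectrum (", n, ")", call. = FALSE)
  }
  sm <- signal::sgolayfilt(spectrum$intensity, p = config$sg_order,
                           n = config$sg_window)
  tibble::tibble(mz = spectrum$mz, intensity = sm)
}

#' Detect centroids in a smoothed spectrum
#'
#' A centroid is reported for every local intensity maximum above the
#' threshold: its m/z is the intensity-weighted mean over the contiguous
#' above-threshold support around the apex (split at local minima when two
#' maxima share a support) and its intensity is the apex intensity.
#'
#' @param spectrum Data frame with columns `mz`, `intensity` (profile-like,
#'   ordered by m/z).
#' @param threshold Baseline threshold; points strictly below are noise.
#' @param config A [preprocess_config()]; `min_peak_points` sets the minimum
#'   support width.
#' @return Tibble of centroids with columns `mz`, `intensity` (possibly
#'   zero rows).
#' @export
detect_centroids <- function(spectrum, threshold,
                             config = preprocess_config()) {
  y <- spectrum$intensity
  mz <- spectrum$mz
  n <- length(y)
  above <- y >= threshold & y > 0
  if (!any(above)) return(tibble::tibble(mz = numeric(), intensity = numeric()))
  # contiguous above-threshold runs
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out_mz <- numeric(0); out_int <- numeric(0)
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    if (i1 - i0 + 1L < config$min_peak_points) next
    seg <- i0:i1
    ys <- y[seg]
    # apexes: strict local maxima within the run (plateau keeps first point)
    is_max <- vapply(seq_along(seg), function(j) {
      left <- if (j == 1) -Inf else ys[j - 1]
      right <- if (j == length(seg)) -Inf else ys[j + 1]
      ys[j] > left && ys[j] >= right
    }, logical(1))
    apexes <- which(is_max)
    if (length(apexes) == 0) apexes <- which.max(ys)
    # split the run at the minimum between consecutive apexes
    cuts <- integer(0)
    if (length(apexes) > 1) {
      for (a in seq_len(length(apexes) - 1)) {
        between <- apexes[a]:apexes[a + 1]
        cuts <- c(cuts, between[which.min(ys[between])])
      }
    }
    bounds <- c(1L, cuts, length(seg))
    for (a in seq_along(apexes)) {
      lo <- bounds[a]; hi <- bounds[a + 1]
      sub <- seg[lo:hi]
      if (length(sub) < config$min_peak_points) next
      w <- y[sub]
      out_mz <- c(out_mz, sum(mz[sub] * w) / sum(w))
      out_int <- c(out_int, y[seg[apexes[a]]])
    }
  }
  ord <- order(out_mz)
  tibble::tibble(mz = out_mz[ord], intensity = out_int[ord])
}

#' Preprocess one spectrum: threshold, smooth, centroid
#'
#' @param spectrum Data frame with columns `mz`, `intensity`.
#' @param config A [preprocess_config()].
#' @return Tibble of centroids.
#' @export
preprocess_spectrum <- function(spectrum, config = preprocess_config()) {
  thr <- kneedle_threshold(spectrum$intensity, config$kneedle_sensitivity)
  sm <- smooth_spectrum(spectrum, config)
  detect_centroids(sm, thr, config)
}
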