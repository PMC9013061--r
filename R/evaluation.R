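# Held-out test-mass evaluation: per-pixel paired absolute-ppm-error
# differences, the Delta-tilde statistic, a bootstrap significance test and
# Benjamini-Hochberg adjustment across datasets.

#' Select held-out test masses near the dominant error mode
#'
#' Pools the per-candidate median relative errors observed in the (original)
#' dataset, locates the dominant error mode with a 1D triangular-kernel KDE
#' and keeps the candidates whose median error lies within `window_ppm` of
#' it. Candidates within 1e-4 Th of any fitting reference are excluded first
#' (the test set must be disjoint from the calibration set).
#'
#' @param candidates Numeric vector of candidate test m/z values.
#' @param dataset The original (uncalibrated) [msi_dataset()].
#' @param roi 0/1 ROI matrix.
#' @param fitting_refs m/z values used to fit the recalibration models.
#' @param search_ppm Match window for locating candidates in the data (same
#'   units as the reference search window).
#' @param window_ppm Half-width of the retained band around the error mode
#'   (default 2.5 ppm).
#' @return Numeric vector of selected test masses (possibly empty, with a
#'   warning).
#' @export
select_test_masses <- function(candidates, dataset, roi, fitting_refs,
                               search_ppm, window_ppm = 2.5) {
  near_ref <- vapply(candidates, function(m) {
    any(abs(m - fitting_refs) < 1e-4)
  }, logical(1))
  candidates <- candidates[!near_ref]
  if (length(candidates) == 0) {
    warning("no candidate test masses left after excluding fitting references")
    return(numeric(0))
  }
  med_err <- vapply(candidates, function(m) {
    hits <- search_reference(dataset, roi, m, search_ppm)
    if (nrow(hits) == 0) return(NA_real_)
    median((hits$mz_obs - m) / m * 1e6)
  }, 0)
  ok <- is.finite(med_err)
  candidates <- candidates[ok]; med_err <- med_err[ok]
  if (length(candidates) == 0) {
    warning("no candidate test masses detected in the dataset")
    return(numeric(0))
  }
  mode <- kde_mode_1d(med_err)
  keep <- abs(med_err - mode) <= window_ppm
  if (!any(keep)) {
    warning("no test masses within the error window; evaluation skipped")
    return(numeric(0))
  }
  candidates[keep]
}

#' Per-pixel paired error differences for a test-mass list
#'
#' Matches each test mass in the original dataset (window `search_ppm`,
#' nearest-in-ppm match when several peaks fall in the window), reads off the
#' recalibrated m/z of the same peak, and returns per (pixel, test mass) the
#' absolute ppm errors before and after.
#'
#' @param original,recalibrated The uncalibrated and recalibrated
#'   [msi_dataset()] objects (same pixels, peak-for-peak).
#' @param roi 0/1 ROI matrix.
#' @param test_masses Numeric vector of test m/z values.
#' @param search_ppm Match window half-width in ppm.
#' @return Tibble with columns `pixel_index`, `test_mz`, `err_before_ppm`,
#'   `err_after_ppm`.
#' @export
test_mass_errors <- function(original, recalibrated, roi, test_masses,
                             search_ppm) {
  recal_split <- split(
    recalibrated$peaks$mz,
    factor(recalibrated$peaks$pixel_index, levels = recalibrated$coords$pixel_index)
  )
  pix_levels <- original$coords$pixel_index
  rows <- lapply(test_masses, function(m) {
    hits <- search_reference(original, roi, m, search_ppm)
    if (nrow(hits) == 0) return(NULL)
    hits$abs_ppm <- abs(hits$mz_obs - m) / m * 1e6
    best <- hits |>
      dplyr::group_by(.data$pixel_index) |>
      dplyr::slice_min(.data$abs_ppm, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
    pi <- match(best$pixel_index, pix_levels)
    # a peak's image under the (monotone) per-pixel calibration map keeps its
    # within-pixel m/z rank, so look the recalibrated mass up by rank
    after_mz <- vapply(seq_len(nrow(best)), function(j) {
      recal_split[[pi[j]]][best$peak_index[j]]
    }, 0)
    tibble::tibble(
      pixel_index = best$pixel_index, test_mz = m,
      err_before_ppm = (best$mz_obs - m) / m * 1e6,
      err_after_ppm = (after_mz - m) / m * 1e6
    )
  })
  dplyr::bind_rows(rows)
}

#' Delta-tilde improvement statistic
#'
#' Per pixel, the median over test masses of
#' `|err_before| - |err_after|` (ppm); Delta-tilde is the median of those
#' per-pixel medians. Positive values mean the recalibration improved mass
#' accuracy.
#'
#' @param errors Tibble from [test_mass_errors()].
#' @return A list with `delta` (the statistic, ppm) and `per_pixel` (tibble
#'   `pixel_index`, `diff_ppm`).
#' @export
delta_statistic <- function(errors) {
  per_pixel <- errors |>
    dplyr::group_by(.data$pixel_index) |>
    dplyr::summarise(
      diff_ppm = median(abs(.data$err_before_ppm) - abs(.data$err_after_ppm)),
      .groups = "drop"
    )
  list(delta = median(per_pixel$diff_ppm), per_pixel = per_pixel)
}

#' Bootstrap test of H0: Delta-tilde = 0
#'
#' Resamples pixels with replacement `B` times and recomputes the median of
#' the per-pixel differences. The two-sided p-value is twice the fraction of
#' bootstrap medians whose sign contradicts the observed statistic, clipped
#' to `[2/B, 1]`.
#'
#' @param per_pixel_diffs Numeric vector of per-pixel median differences
#'   (ppm), length >= 10.
#' @param B Number of bootstrap repetitions (default 10,000).
#' @param seed Seed for the resampling.
#' @return A list with `p_value`, `delta` (observed median), `boot_medians`.
#' @export
bootstrap_test <- function(per_pixel_diffs, B = 10000L, seed = 1L) {
  n <- length(per_pixel_diffs)
  stopifnot(n >= 10)
  obs <- median(per_pixel_diffs)
  boot <- withr::with_seed(seed, {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
    m <- matrix(per_pixel_diffs[idx], nrow = n)
    apply(m, 2, median)
  })
  p <- if (obs > 0) 2 * mean(boot <= 0)
  else if (obs < 0) 2 * mean(boot >= 0)
  else 1
  p <- min(1, max(2 / B, p))
  list(p_value = p, delta = obs, boot_medians = boot)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment across datasets.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (same order as input).
#' @export
bh_adjust <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  stats::p.adjust(pvalues, method = "BH")
}

#' Evaluate a recalibration on held-out test masses
#'
#' @inheritParams test_mass_errors
#' @param B Bootstrap repetitions.
#' @param seed Bootstrap seed.
#' @return Object of class `recal_evaluation`: Delta-tilde, bootstrap
#'   p-value, per-pixel differences and before/after error summaries.
#' @export
evaluate_recalibration <- function(original, recalibrated, roi, test_masses,
                                   search_ppm, B = 10000L, seed = 1L) {
  errors <- test_mass_errors(original, recalibrated, roi, test_masses, search_ppm)
  if (nrow(errors) == 0) stop("no test-mass matches found", call. = FALSE)
  ds <- delta_statistic(errors)
  bt <- bootstrap_test(ds$per_pixel$diff_ppm, B = B, seed = seed)
  structure(
    list(
      delta = ds$delta, p_value = bt$p_value,
      per_pixel = ds$per_pixel, errors = errors,
      median_abs_before = median(abs(errors$err_before_ppm)),
      median_abs_after = median(abs(errors$err_after_ppm)),
      n_pixels = nrow(ds$per_pixel), n_test_masses = length(test_masses),
      B = B, seed = seed
    ),
    class = "recal_evaluation"
  )
}

#' @export
print.recal_evaluation <- function(x, ...) {
  cat(sprintf(
    paste0("<recal_evaluation> Delta-tilde = %.3f ppm | p = %.4g | ",
           "median |error| %.3f -> %.3f ppm | %d pixels, %d test masses\n"),
    x$delta, x$p_value, x$median_abs_before, x$median_abs_after,
    x$n_pixels, x$n_test_masses
  ))
  invisible(x)
}

#' @rdname glance
#' @export
glance.recal_evaluation <- function(x, ...) {
  tibble::tibble(
    delta_ppm = x$delta, p_value = x$p_value,
    median_abs_before_ppm = x$median_abs_before,
    median_abs_after_ppm = x$median_abs_after,
    n_pixels = x$n_pixels, n_test_masses = x$n_test_masses, B = x$B
  )
}

#' @rdname tidy
#' @export
tidy.recal_evaluation <- function(x, ...) x$errors
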