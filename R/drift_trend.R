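# Drift-track modelling for one candidate reference mass: cubic ridge spline
# on the KDE maxima, MAD-based outlier rejection, coverage/dispersion
# acceptance rule, and the penalized-spline GAM drift trend.

#' Fit the cubic ridge spline on KDE maxima
#'
#' A cubic smoothing spline is fitted to the `(pixel, mass)` local maxima of
#' the drift-track KDE. The smoothing parameter is chosen by fivefold
#' cross-validation over 30 values from 1e-5 to 0.1, evenly spaced on the
#' log10 scale (smallest CV mean squared error wins).
#'
#' @param maxima Tibble from [trace_ridge()] with columns `x`, `y` (>= 5
#'   rows).
#' @param lambda_grid Candidate smoothing parameters.
#' @param folds Number of CV folds.
#' @param seed Seed for the random fold assignment (recorded in the result).
#' @return Object of class `ridge_spline`: the selected `smooth.spline` fit
#'   plus `lambda`, `cv_mse` and `seed`.
#' @export
fit_ridge_spline <- function(maxima,
                             lambda_grid = 10^seq(log10(1e-5), log10(0.1), length.out = 30),
                             folds = 5L, seed = 42L) {
  n <- nrow(maxima)
  if (n < 5) stop("need at least 5 KDE maxima to fit the ridge spline", call. = FALSE)
  x <- maxima$x; y <- maxima$y
  fold_id <- withr::with_seed(seed, sample(rep_len(seq_len(folds), n)))
  cv_mse <- vapply(lambda_grid, function(lam) {
    errs <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      if (sum(tr) < 4 || length(unique(x[tr])) < 4) return(NA_real_)
      fit <- tryCatch(
        stats::smooth.spline(x[tr], y[tr], lambda = lam, cv = FALSE,
                             all.knots = TRUE, keep.data = FALSE),
        error = function(e) NULL
      )
      if (is.null(fit)) return(NA_real_)
      mean((predict(fit, x[!tr])$y - y[!tr])^2)
    }, 0)
    mean(errs, na.rm = TRUE)
  }, 0)
  lambda <- lambda_grid[which.min(cv_mse)]
  fit <- stats::smooth.spline(x, y, lambda = lambda, cv = FALSE,
                              all.knots = TRUE, keep.data = FALSE)
  structure(
    list(fit = fit, lambda = lambda, cv_mse = cv_mse,
         lambda_grid = lambda_grid, seed = seed,
         range = range(x)),
    class = "ridge_spline"
  )
}

#' @export
predict.ridge_spline <- function(object, x, ...) {
  predict(object$fit, x)$y
}

#' Flag drift-track outliers against the ridge spline
#'
#' Absolute residuals `r_i = |mz_obs_i - S(p_i)|` are computed against the
#' spline; points with `r_i >= 2 * mad(r)` are outliers. The residuals are
#' already absolute deviations about the spline, so the median absolute
#' deviation is `median(r)` scaled by the normal consistency factor 1.4826
#' (a robust estimate of the noise SD; the rule is then the classic
#' two-sigma cut, and the dispersion threshold below is commensurate with
#' measurement noise). When `mad(r) = 0`, only points with a strictly
#' positive residual are flagged, so perfect fits are kept. The per-point
#' dispersion `d_i = 2 * mad(r_inlier) / S(p_i) * 1e6` (ppm) is computed from
#' the post-filter residuals.
#'
#' @param matches Match table from [search_reference()] (columns
#'   `pixel_index`, `mz_obs`, ...).
#' @param spline A [fit_ridge_spline()] object.
#' @return The match table with added columns `spline_mz`, `residual`,
#'   `inlier`, `dispersion_ppm`, plus attributes `mad_r` (Da) and
#'   `max_dispersion_ppm`.
#' @export
flag_outliers <- function(matches, spline) {
  s <- predict(spline, matches$pixel_index)
  r <- abs(matches$mz_obs - s)
  # r is an absolute deviation about the spline already: center at 0.
  # A mad at floating-point noise level (perfect fits) counts as zero, so
  # machine-epsilon residuals are not flagged.
  tol <- 1e-12 * stats::median(abs(s))
  mad_r <- mad(r, center = 0)
  inlier <- if (mad_r <= tol) r <= tol else r < 2 * mad_r
  mad_in <- mad(r[inlier], center = 0)
  if (mad_in <= tol) mad_in <- 0
  disp <- ifelse(inlier, 2 * mad_in / s * 1e6, NA_real_)
  out <- dplyr::mutate(matches, spline_mz = s, residual = r,
                       inlier = inlier, dispersion_ppm = disp)
  attr(out, "reference_mz") <- attr(matches, "reference_mz")
  attr(out, "mad_r") <- mad_r
  attr(out, "max_dispersion_ppm") <- if (any(inlier)) max(disp[inlier]) else Inf
  out
}

#' MAD normal-consistency factor
#'
#' The constant `1 / qnorm(3/4)` that scales the raw median absolute
#' deviation to a consistent estimator of the standard deviation under
#' normality.
#'
#' @return The consistency factor (about 1.4826).
#' @export
mad_consistency_factor <- function() 1 / stats::qnorm(3 / 4)

#' Accept or reject a candidate reference
#'
#' A reference is kept iff (a) its distinct inlier pixels cover at least
#' `min_frac` of the ROI and (b) the maximum inlier dispersion does not
#' exceed `max_dispersion_ppm`.
#'
#' @param diagnostics Output of [flag_outliers()].
#' @param n_roi Number of ROI pixels.
#' @param min_frac Minimum inlier pixel fraction (default 0.75).
#' @param max_dispersion_ppm Dispersion ceiling in ppm (default 10,
#'   user-customizable).
#' @return Logical scalar.
#' @export
accept_reference <- function(diagnostics, n_roi, min_frac = 0.75,
                             max_dispersion_ppm = 10) {
  n_inlier_pixels <- length(unique(diagnostics$pixel_index[diagnostics$inlier]))
  d_max <- attr(diagnostics, "max_dispersion_ppm")
  n_inlier_pixels >= min_frac * n_roi && d_max <= max_dispersion_ppm
}

#' Fit the GAM drift trend of an accepted reference
#'
#' Gaussian additive model of the observed inlier masses over pixel order,
#' with an intercept and 20 penalized cubic regression spline terms. The
#' smoothing penalty is selected by GCV among eleven values between 0.001 and
#' 1000, evenly spaced on the log10 scale, and the selected model predicts
#' the reference's observed m/z at every ROI pixel.
#'
#' @param diagnostics Output of [flag_outliers()]; only inliers are used.
#' @param roi_pixels Integer vector of all ROI `pixel_index` values at which
#'   to predict.
#' @param k Spline basis dimension (default 20).
#' @param sp_grid Candidate smoothing penalties.
#' @return Object of class `drift_trend`: the selected `mgcv::gam` fit,
#'   selected penalty `sp`, `gcv` values, the reference m/z and a tibble
#'   `predictions` (`pixel_index`, `mz_pred`).
#' @export
fit_gam_trend <- function(diagnostics, roi_pixels, k = 20L,
                          sp_grid = 10^seq(-3, 3, length.out = 11)) {
  d <- diagnostics[diagnostics$inlier, ]
  df <- data.frame(p = d$pixel_index, mz = d$mz_obs)
  kk <- min(k, max(3L, length(unique(df$p)) - 1L))
  fits <- lapply(sp_grid, function(sp) {
    tryCatch(
      mgcv::gam(mz ~ s(p, bs = "cr", k = kk), data = df, sp = sp,
                method = "GCV.Cp"),
      error = function(e) NULL
    )
  })
  gcv <- vapply(fits, function(f) if (is.null(f)) Inf else f$gcv.ubre, 0)
  if (all(!is.finite(gcv))) {
    stop("GAM drift trend failed to converge for reference ",
         attr(diagnostics, "reference_mz"), call. = FALSE)
  }
  best <- which.min(gcv)
  fit <- fits[[best]]
  pred <- as.numeric(predict(fit, newdata = data.frame(p = roi_pixels)))
  if (any(!is.finite(pred))) {
    stop("non-finite GAM predictions for reference ",
         attr(diagnostics, "reference_mz"), call. = FALSE)
  }
  structure(
    list(
      gam = fit, sp = sp_grid[best], gcv = gcv, sp_grid = sp_grid,
      reference_mz = attr(diagnostics, "reference_mz"),
      sigma2 = fit$sig2,
      predictions = tibble::tibble(pixel_index = roi_pixels, mz_pred = pred)
    ),
    class = "drift_trend"
  )
}

#' @export
print.drift_trend <- function(x, ...) {
  cat(sprintf("<drift_trend> reference %.4f m/z | sp = %g | sigma = %.2e\n",
              x$reference_mz, x$sp, sqrt(x$sigma2)))
  invisible(x)
}

#' @rdname tidy
#' @param x A `drift_trend` object.
#' @param ... Unused.
#' @export
tidy.drift_trend <- function(x, ...) x$predictions

#' @rdname glance
#' @param x A `drift_trend` object.
#' @param ... Unused.
#' @export
glance.drift_trend <- function(x, ...) {
  tibble::tibble(
    reference_mz = x$reference_mz, sp = x$sp,
    sigma = sqrt(x$sigma2), gcv = min(x$gcv),
    n_inliers = stats::nobs(x$gam)
  )
}

#' Model one candidate reference's drift track end to end
#'
#' Runs the KDE -> ridge -> spline -> outlier -> acceptance chain for one
#' match table and, if the reference is accepted, fits its GAM drift trend.
#'
#' @param matches Match table from [search_reference()].
#' @param roi_pixels Integer vector of ROI `pixel_index` values.
#' @param G KDE grid size.
#' @param min_frac Inlier coverage threshold.
#' @param max_dispersion_ppm Dispersion threshold (ppm).
#' @param spline_seed Seed for the ridge-spline CV folds.
#' @return A list with `accepted` (logical), `diagnostics`, and (when
#'   accepted) `trend`; `NULL` diagnostics when the track could not be
#'   modelled at all (fewer than 5 KDE maxima).
#' @export
model_reference_track <- function(matches, roi_pixels, G = 1024L,
                                  min_frac = 0.75, max_dispersion_ppm = 10,
                                  spline_seed = 42L) {
  res <- list(accepted = FALSE, diagnostics = NULL, trend = NULL,
              reference_mz = attr(matches, "reference_mz"))
  if (nrow(matches) < 5) return(res)
  kde <- fit_fft_kde(cbind(matches$pixel_index, matches$mz_obs), G = G)
  ridge <- trace_ridge(kde)
  if (nrow(ridge) < 5) return(res)
  spline <- tryCatch(fit_ridge_spline(ridge, seed = spline_seed),
                     error = function(e) NULL)
  if (is.null(spline)) return(res)
  diag <- flag_outliers(matches, spline)
  res$diagnostics <- diag
  if (!accept_reference(diag, length(roi_pixels), min_frac, max_dispersion_ppm)) {
    return(res)
  }
  trend <- tryCatch(fit_gam_trend(diag, roi_pixels),
                    error = function(e) NULL)
  if (is.null(trend)) return(res)
  res$accepted <- TRUE
  res$trend <- trend
  res
}
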