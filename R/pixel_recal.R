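# Per-pixel calibration: select the GAM-predicted references sharing a common
# relative error, fit the analyzer-specific model (linear for Orbitrap,
# sqrt-domain polynomial with BIC degree selection for TOF) and map every
# observed mass in the pixel through it.

#' Filter a pixel's references to the dominant common-error mode
#'
#' Relative errors `e_k = (mz_pred_k - mz_theo_k) / mz_theo_k * 1e6` (ppm) are
#' pooled; the dominant error mode is the argmax of a 1D triangular-kernel
#' KDE over them (ties resolved toward the lower ppm value) and only
#' references with `|e_k - mode| <= band_ppm` are retained. If fewer than two
#' survive, the unfiltered set is returned with a warning so the pixel can
#' still be recalibrated.
#'
#' @param refs Tibble with columns `mz_theo` (theoretical reference m/z) and
#'   `mz_pred` (GAM-predicted observed m/z at this pixel), >= 2 rows.
#' @param band_ppm Half-width of the retained error band around the mode
#'   (default 2.5 ppm for Orbitrap, 10 for TOF in [recal_config()]).
#' @return The filtered tibble with an added `error_ppm` column.
#' @export
filter_common_error <- function(refs, band_ppm) {
  stopifnot(nrow(refs) >= 2)
  e <- (refs$mz_pred - refs$mz_theo) / refs$mz_theo * 1e6
  refs$error_ppm <- e
  mode <- kde_mode_1d(e)
  keep <- abs(e - mode) <= band_ppm
  if (sum(keep) < 2) {
    warning("common-error filter left < 2 references; using the unfiltered set")
    return(refs)
  }
  refs[keep, ]
}

#' Fit the Orbitrap per-pixel calibration model
#'
#' Ordinary least squares of the theoretical reference masses on the
#' GAM-predicted observed masses: `mz_theo ~ beta0 + beta1 * mz_pred`.
#'
#' @param refs Filtered tibble with columns `mz_theo`, `mz_pred` (>= 2 rows).
#' @return Object of class `pixel_recal_model` with `analyzer = "orbitrap"`,
#'   `coefficients`, `degree = 1`, residual variance and the covered m/z
#'   range.
#' @export
fit_orbitrap_model <- function(refs) {
  stopifnot(nrow(refs) >= 2)
  x <- refs$mz_pred
  if (diff(range(x)) == 0) {
    stop("degenerate design: all predicted reference masses equal", call. = FALSE)
  }
  X <- cbind(1, x)
  fit <- .lm.fit(X, refs$mz_theo)
  rss <- sum(fit$residuals^2)
  structure(
    list(
      analyzer = "orbitrap", coefficients = fit$coefficients, degree = 1L,
      sigma2 = rss / max(1, nrow(refs) - 2), n_refs = nrow(refs),
      mz_range = range(x), bic = NULL
    ),
    class = "pixel_recal_model"
  )
}

.bic_ols <- function(rss, n, n_coef) n * log(rss / n) + n_coef * log(n)

#' Fit the TOF per-pixel calibration model
#'
#' Polynomial regression in the square-root mass domain:
#' `sqrt(mz_theo) ~ beta0 + sum_d beta_d * sqrt(mz_pred)^d`, with the degree
#' `D <= max_degree` chosen by the smallest BIC
#' (`n log(RSS/n) + (D+1) log n`). Each candidate degree needs at least
#' `D + 2` references; ill-conditioned degrees are skipped.
#'
#' @param refs Filtered tibble with columns `mz_theo`, `mz_pred` (>= 3 rows).
#' @param max_degree Largest polynomial degree considered (default 5).
#' @return Object of class `pixel_recal_model` with `analyzer = "tof"`, the
#'   BIC-selected coefficients and degree, and the per-degree BIC table.
#' @export
fit_tof_model <- function(refs, max_degree = 5L) {
  stopifnot(nrow(refs) >= 3)
  n <- nrow(refs)
  s_obs <- sqrt(refs$mz_pred)
  s_theo <- sqrt(refs$mz_theo)
  degrees <- seq_len(min(max_degree, n - 2L))
  cand <- lapply(degrees, function(D) {
    X <- stats::poly(s_obs, degree = D, raw = TRUE)
    X <- cbind(1, X)
    fit <- tryCatch(.lm.fit(X, s_theo), error = function(e) NULL)
    if (is.null(fit) || any(!is.finite(fit$coefficients))) return(NULL)
    # floor the RSS at the double-precision noise of the response so that
    # exact fits do not make the log-likelihood term degenerate (the
    # penalty then decides, favouring the smallest adequate degree)
    rss_floor <- n * (1e-12 * mean(abs(s_theo)))^2
    rss <- max(sum(fit$residuals^2), rss_floor)
    list(D = D, coef = fit$coefficients, bic = .bic_ols(rss, n, D + 1L))
  })
  cand <- cand[!vapply(cand, is.null, TRUE)]
  if (length(cand) == 0) {
    stop("no TOF calibration degree could be fitted", call. = FALSE)
  }
  bics <- vapply(cand, `[[`, 0, "bic")
  best <- cand[[which.min(bics)]]
  structure(
    list(
      analyzer = "tof", coefficients = best$coef, degree = best$D,
      n_refs = n, mz_range = range(refs$mz_pred),
      bic = stats::setNames(bics, vapply(cand, `[[`, 0L, "D"))
    ),
    class = "pixel_recal_model"
  )
}

#' Apply a per-pixel calibration model to a spectrum
#'
#' Orbitrap: `mz_cal = beta0 + beta1 * mz`. TOF: the sqrt-domain polynomial
#' prediction is squared back; a non-positive sqrt-domain prediction leaves
#' that peak uncorrected (flagged via the `corrected` attribute). Intensities
#' are untouched; output is re-sorted by m/z if the mapping perturbs order.
#'
#' @param model A `pixel_recal_model`.
#' @param spectrum Tibble with columns `mz`, `intensity`.
#' @return Tibble with recalibrated `mz`, original `intensity`; attribute
#'   `corrected` (logical per input peak, in input order).
#' @export
apply_model <- function(model, spectrum) {
  mz <- spectrum$mz
  if (length(mz) == 0) {
    out <- spectrum
    attr(out, "corrected") <- logical(0)
    return(out)
  }
  if (model$analyzer == "orbitrap") {
    b <- model$coefficients
    new_mz <- b[1] + b[2] * mz
    corrected <- rep(TRUE, length(mz))
  } else {
    b <- model$coefficients
    s <- sqrt(mz)
    pred <- as.vector(outer(s, seq_along(b) - 1, "^") %*% b)
    corrected <- pred > 0
    new_mz <- ifelse(corrected, pred^2, mz)
  }
  ord <- order(new_mz)
  out <- tibble::tibble(mz = new_mz[ord], intensity = spectrum$intensity[ord])
  attr(out, "corrected") <- corrected
  out
}

#' @export
print.pixel_recal_model <- function(x, ...) {
  cat(sprintf("<pixel_recal_model> %s | degree %d | %d refs | m/z %.3f-%.3f\n",
              x$analyzer, x$degree, x$n_refs, x$mz_range[1], x$mz_range[2]))
  invisible(x)
}

#' Recalibrate every ROI pixel of a dataset
#'
#' For each ROI pixel: assemble the GAM-predicted reference masses, apply the
#' common-error filter, fit the analyzer-specific model and map all the
#' pixel's observed masses through it. Off-sample pixels pass through
#' unchanged.
#'
#' @param dataset An [msi_dataset()].
#' @param roi 0/1 ROI matrix.
#' @param trends List of accepted [fit_gam_trend()] objects.
#' @param config A [recal_config()].
#' @return A list with `dataset` (the recalibrated [msi_dataset()]) and
#'   `models`, a tibble of per-pixel fit summaries (`pixel_index`, `degree`,
#'   `n_refs`, `mz_lo`, `mz_hi`, coefficient columns `b0..`, `fitted`).
#' @export
recalibrate_pixels <- function(dataset, roi, trends, config = recal_config()) {
  if (length(trends) == 0) {
    stop("zero accepted references: cannot recalibrate", call. = FALSE)
  }
  roi_pix <- roi_pixel_indices(dataset, roi)
  mz_theo <- vapply(trends, `[[`, 0, "reference_mz")
  pred_mat <- vapply(trends, function(t) {
    t$predictions$mz_pred[match(roi_pix, t$predictions$pixel_index)]
  }, numeric(length(roi_pix)))
  if (length(roi_pix) == 1) pred_mat <- matrix(pred_mat, nrow = 1)

  analyzer <- dataset$analyzer
  band <- config$error_band_ppm %||%
    (if (analyzer == "orbitrap") 2.5 else 10)
  max_coef <- 6L
  peaks_split <- split(
    dataset$peaks,
    factor(dataset$peaks$pixel_index, levels = dataset$coords$pixel_index)
  )
  pix_all <- dataset$coords$pixel_index
  new_peaks <- vector("list", length(pix_all))
  model_rows <- vector("list", length(roi_pix))
  roi_set <- match(pix_all, roi_pix)

  for (i in seq_along(pix_all)) {
    p <- pix_all[i]
    sp <- peaks_split[[i]][c("mz", "intensity")]
    r <- roi_set[i]
    if (is.na(r)) {
      new_peaks[[i]] <- sp
      next
    }
    refs <- tibble::tibble(mz_theo = mz_theo, mz_pred = pred_mat[r, ])
    model <- tryCatch({
      filt <- withCallingHandlers(
        filter_common_error(refs, band),
        warning = function(w) invokeRestart("muffleWarning")
      )
      if (analyzer == "orbitrap") fit_orbitrap_model(filt)
      else fit_tof_model(filt, config$max_degree)
    }, error = function(e) NULL)
    if (is.null(model)) {
      new_peaks[[i]] <- sp
      model_rows[[r]] <- tibble::tibble(
        pixel_index = p, fitted = FALSE, degree = NA_integer_,
        n_refs = NA_integer_, mz_lo = NA_real_, mz_hi = NA_real_
      )
      next
    }
    new_peaks[[i]] <- apply_model(model, sp)
    co <- c(model$coefficients, rep(NA_real_, max_coef))[seq_len(max_coef)]
    model_rows[[r]] <- tibble::tibble(
      pixel_index = p, fitted = TRUE, degree = model$degree,
      n_refs = model$n_refs,
      mz_lo = model$mz_range[1], mz_hi = model$mz_range[2],
      !!!stats::setNames(as.list(co), paste0("b", 0:(max_coef - 1)))
    )
  }

  npk <- vapply(new_peaks, nrow, 0L)
  peaks <- tibble::tibble(
    pixel_index = rep(pix_all, npk),
    mz = unlist(lapply(new_peaks, `[[`, "mz"), use.names = FALSE),
    intensity = unlist(lapply(new_peaks, `[[`, "intensity"), use.names = FALSE)
  )
  out <- msi_dataset(peaks, dataset$coords, dataset$n_rows, dataset$n_cols,
                     dataset$polarity, dataset$analyzer)
  list(dataset = out, models = dplyr::bind_rows(model_rows))
}
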