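# End-to-end orchestration of the recalibration workflow:
# search -> coverage filter -> KDE/ridge/outliers/acceptance -> GAM trends ->
# per-pixel common-error filter + calibration fit -> apply -> (evaluate).

#' Recalibration configuration
#'
#' Defaults follow the published workflow settings: 20 ppm search window for
#' Orbitrap and 100 ppm for TOF, 75% coverage, 10 ppm dispersion ceiling,
#' 1024-point KDE grid, 20 GAM spline terms with an 11-value penalty grid,
#' 2.5 ppm evaluation window and 10,000 bootstrap repetitions.
#'
#' @param analyzer `"orbitrap"` or `"tof"`.
#' @param window_ppm Reference search window half-width (ppm); default 20
#'   (Orbitrap) or 100 (TOF).
#' @param coverage Minimum fraction of ROI pixels a reference must cover.
#' @param dispersion_ppm Ceiling on the inlier dispersion around the ridge
#'   spline.
#' @param kde_grid KDE grid size G.
#' @param gam_k Number of GAM spline terms.
#' @param gam_sp_grid GAM penalty grid.
#' @param spline_lambda_grid Ridge-spline smoothing grid.
#' @param error_band_ppm Half-width of the per-pixel common-error band;
#'   default 2.5 (Orbitrap) or 10 (TOF).
#' @param max_degree Maximum TOF polynomial degree.
#' @param eval_window_ppm Test-mass selection window (ppm).
#' @param bootstrap_B Bootstrap repetitions for the evaluation.
#' @param seed Root seed for the stochastic sub-steps (spline CV folds,
#'   bootstrap).
#' @return A list of class `recal_config`.
#' @export
recal_config <- function(analyzer = c("orbitrap", "tof"),
                         window_ppm = NULL,
                         coverage = 0.75,
                         dispersion_ppm = 10,
                         kde_grid = 1024L,
                         gam_k = 20L,
                         gam_sp_grid = 10^seq(-3, 3, length.out = 11),
                         spline_lambda_grid = 10^seq(log10(1e-5), log10(0.1),
                                                     length.out = 30),
                         error_band_ppm = NULL,
                         max_degree = 5L,
                         eval_window_ppm = 2.5,
                         bootstrap_B = 10000L,
                         seed = 1L) {
  analyzer <- match.arg(analyzer)
  window_ppm <- window_ppm %||% (if (analyzer == "orbitrap") 20 else 100)
  stopifnot(window_ppm > 0, coverage > 0, dispersion_ppm > 0, kde_grid >= 64)
  structure(
    list(
      analyzer = analyzer, window_ppm = window_ppm, coverage = coverage,
      dispersion_ppm = dispersion_ppm, kde_grid = as.integer(kde_grid),
      gam_k = as.integer(gam_k), gam_sp_grid = gam_sp_grid,
      spline_lambda_grid = spline_lambda_grid,
      error_band_ppm = error_band_ppm, max_degree = as.integer(max_degree),
      eval_window_ppm = eval_window_ppm,
      bootstrap_B = as.integer(bootstrap_B), seed = as.integer(seed)
    ),
    class = "recal_config"
  )
}

#' Recalibrate an MSI dataset against a reference mass list
#'
#' The main entry point of the package: runs the reference search, coverage
#' filter, KDE/ridge/outlier acceptance, GAM drift-trend fitting and
#' per-pixel recalibration, and returns the recalibrated dataset together
#' with all per-stage diagnostics.
#'
#' @param dataset An [msi_dataset()].
#' @param roi 0/1 ROI matrix (`n_rows x n_cols`).
#' @param reference_mzs Candidate reference m/z values (e.g. from
#'   [expand_adducts()]).
#' @param config A [recal_config()]; its `analyzer` must match the dataset.
#' @return Object of class `msi_recal`: list with `dataset` (recalibrated),
#'   `original`, `trends` (accepted drift trends), `reference_diagnostics`
#'   (per-candidate tibble: m/z, coverage, max dispersion, inlier count,
#'   accepted flag), `pixel_models` (per-pixel fit summaries) and `config`.
#' @export
recalibrate_msi <- function(dataset, roi, reference_mzs,
                            config = recal_config(dataset$analyzer)) {
  stopifnot(inherits(dataset, "msi_dataset"))
  if (config$analyzer != dataset$analyzer) {
    stop("config analyzer (", config$analyzer, ") does not match dataset (",
         dataset$analyzer, ")", call. = FALSE)
  }
  roi_pix <- roi_pixel_indices(dataset, roi)
  n_roi <- length(roi_pix)
  if (n_roi == 0) stop("ROI mask selects no pixels", call. = FALSE)

  tables <- search_references(dataset, roi, reference_mzs, config$window_ppm)
  coverage <- vapply(tables, attr, 0, "coverage")
  covered <- coverage_filter(tables, n_roi, config$coverage)

  tracks <- lapply(covered, function(tab) {
    model_reference_track(
      tab, roi_pix, G = config$kde_grid,
      min_frac = config$coverage,
      max_dispersion_ppm = config$dispersion_ppm,
      spline_seed = config$seed
    )
  })
  accepted <- Filter(function(t) t$accepted, tracks)
  trends <- lapply(accepted, `[[`, "trend")

  diag_proto <- tibble::tibble(
    reference_mz = numeric(), n_matches = integer(),
    n_inlier_pixels = integer(), max_dispersion_ppm = numeric(),
    accepted = logical()
  )
  diag_rows <- lapply(tracks, function(t) {
    d <- t$diagnostics
    tibble::tibble(
      reference_mz = t$reference_mz,
      n_matches = if (is.null(d)) NA_integer_ else nrow(d),
      n_inlier_pixels = if (is.null(d)) NA_integer_ else
        length(unique(d$pixel_index[d$inlier])),
      max_dispersion_ppm = if (is.null(d)) NA_real_ else
        attr(d, "max_dispersion_ppm"),
      accepted = t$accepted
    )
  })
  reference_diagnostics <- tibble::tibble(
    reference_mz = vapply(tables, attr, 0, "reference_mz"),
    coverage = coverage
  ) |>
    dplyr::left_join(dplyr::bind_rows(diag_proto, diag_rows),
                     by = "reference_mz") |>
    dplyr::mutate(accepted = !is.na(.data$accepted) & .data$accepted)

  if (length(trends) == 0) {
    stop("zero accepted references after track filtering; ",
         "cannot recalibrate (", sum(coverage >= config$coverage),
         " of ", length(tables), " candidates passed coverage)", call. = FALSE)
  }

  recal <- recalibrate_pixels(dataset, roi, trends, config)
  structure(
    list(
      dataset = recal$dataset, original = dataset, roi = roi,
      trends = trends, reference_diagnostics = reference_diagnostics,
      pixel_models = recal$models, config = config,
      track_details = tracks
    ),
    class = "msi_recal"
  )
}

#' @export
print.msi_recal <- function(x, ...) {
  cat(sprintf(
    "<msi_recal> %s | %d/%d candidate references accepted | %d pixels recalibrated\n",
    x$config$analyzer, length(x$trends), nrow(x$reference_diagnostics),
    sum(x$pixel_models$fitted)
  ))
  invisible(x)
}

#' @rdname tidy
#' @export
tidy.msi_recal <- function(x, ...) x$pixel_models

#' @rdname glance
#' @export
glance.msi_recal <- function(x, ...) {
  tibble::tibble(
    analyzer = x$config$analyzer,
    n_candidates = nrow(x$reference_diagnostics),
    n_covered = sum(x$reference_diagnostics$coverage >= x$config$coverage),
    n_accepted = length(x$trends),
    n_pixels_fitted = sum(x$pixel_models$fitted),
    median_degree = median(x$pixel_models$degree, na.rm = TRUE),
    window_ppm = x$config$window_ppm
  )
}

#' Run the full pipeline from files
#'
#' File-level orchestration used by the command-line interface: reads the
#' imzML dataset, the ROI mask (or trains one from pixel labels), expands the
#' reference database, recalibrates, optionally evaluates against test
#' masses, and writes the recalibrated imzML plus TSV diagnostics and a run
#' manifest to `out_dir`.
#'
#' @param imzml_path Input imzML file.
#' @param db_path Reference database CSV (see [read_reference_db()]).
#' @param out_dir Output directory (created if missing).
#' @param roi_path Optional ROI mask CSV.
#' @param labels_path Optional pixel-label CSV (used when `roi_path` is
#'   missing).
#' @param analyzer Analyzer override for files that do not record one.
#' @param config A [recal_config()]; built from the analyzer if `NULL`.
#' @param test_masses Optional held-out test m/z values for evaluation.
#' @return The `msi_recal` object, invisibly; artifacts on disk.
#' @export
run_recal_pipeline <- function(imzml_path, db_path, out_dir,
                               roi_path = NULL, labels_path = NULL,
                               analyzer = NULL, config = NULL,
                               test_masses = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dataset <- read_imzml(imzml_path, analyzer = analyzer)
  config <- config %||% recal_config(dataset$analyzer)

  roi <- if (!is.null(roi_path)) {
    read_roi_mask(roi_path, dataset$n_rows, dataset$n_cols)
  } else if (!is.null(labels_path)) {
    select_roi(dataset, read_pixel_labels(labels_path))
  } else {
    stop("either roi_path or labels_path is required", call. = FALSE)
  }

  db <- read_reference_db(db_path)
  cand <- expand_adducts(db, dataset$polarity)
  res <- recalibrate_msi(dataset, roi, cand$mz, config)

  write_imzml(res$dataset, file.path(out_dir, "recalibrated"))
  utils::write.table(res$reference_diagnostics,
                     file.path(out_dir, "reference_diagnostics.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(res$pixel_models,
                     file.path(out_dir, "pixel_models.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_roi_mask(roi, file.path(out_dir, "roi.csv"))

  eval_res <- NULL
  if (!is.null(test_masses)) {
    kept <- select_test_masses(
      test_masses, dataset, roi,
      fitting_refs = vapply(res$trends, `[[`, 0, "reference_mz"),
      search_ppm = config$window_ppm,
      window_ppm = config$eval_window_ppm
    )
    if (length(kept) > 0) {
      eval_res <- evaluate_recalibration(
        dataset, res$dataset, roi, kept,
        search_ppm = config$window_ppm,
        B = config$bootstrap_B, seed = config$seed
      )
      utils::write.table(glance(eval_res),
                         file.path(out_dir, "evaluation.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }

  manifest <- c(
    sprintf("msirecal %s", as.character(utils::packageVersion("msirecal"))),
    sprintf("input: %s", imzml_path),
    sprintf("analyzer: %s", config$analyzer),
    sprintf("window_ppm: %g", config$window_ppm),
    sprintf("coverage: %g", config$coverage),
    sprintf("dispersion_ppm: %g", config$dispersion_ppm),
    sprintf("kde_grid: %d", config$kde_grid),
    sprintf("seed: %d", config$seed),
    sprintf("candidates: %d", nrow(res$reference_diagnostics)),
    sprintf("accepted_references: %d", length(res$trends)),
    sprintf("pixels_fitted: %d", sum(res$pixel_models$fitted))
  )
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  res$evaluation <- eval_res
  invisible(res)
}
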