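# Synthetic MSI datasets with planted, known drift: the ground truth against
# which every stage of the recalibration workflow is tested. The generator
# emulates smooth pixel-order-dependent mass drift (multiplicative ppm-domain
# for Orbitrap, sqrt-m-domain for TOF), per-pixel Bernoulli reference
# detection, ppm-scale measurement noise, decoy interferent peaks with
# complementary spatial masks, and off-sample background pixels.

#' Simulation configuration
#'
#' @param n_rows,n_cols Pixel grid dimensions.
#' @param roi_fraction Fraction of grid rows occupied by the on-sample block
#'   (a contiguous band of rows, so the ROI pixel count is exact).
#' @param analyzer `"orbitrap"` or `"tof"`; decides the drift domain.
#' @param reference_mzs Theoretical m/z values of the planted reference ions.
#' @param drift_amplitude_ppm Peak drift amplitude in ppm (0 = drift-free).
#' @param drift_period_pixels Period of the sinusoidal pixel-order drift.
#' @param drift_phase Phase of the drift sinusoid (radians).
#' @param mass_curvature For TOF: weights `c(w0, w1, w2)` of the
#'   mass-dependence of the drift as a polynomial in the scaled sqrt-mass;
#'   normalised so the maximum over the mass range is 1. Orbitrap drift is
#'   mass-independent (purely multiplicative).
#' @param noise_sigma_ppm Standard deviation of the ppm measurement noise.
#' @param detection_prob Per-reference, per-pixel Bernoulli detection
#'   probability.
#' @param n_decoys Number of decoy interferent ions.
#' @param decoy_offset_ppm Range of fixed ppm offsets at which decoys sit
#'   next to randomly chosen references.
#' @param decoy_coverage Fraction of ROI pixels (one contiguous block) in
#'   which each decoy is detected, complementary in space to nothing else.
#' @param background_peaks Number of random background peaks per off-sample
#'   pixel.
#' @param intensity_meanlog,intensity_sdlog Log-normal intensity model.
#' @param polarity Ionisation polarity recorded in the dataset.
#' @param seed Mandatory RNG seed; the generator is deterministic given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_rows = 50L, n_cols = 50L, roi_fraction = 0.8,
                       analyzer = c("orbitrap", "tof"),
                       reference_mzs = default_reference_mzs(),
                       drift_amplitude_ppm = 5,
                       drift_period_pixels = NULL,
                       drift_phase = 0,
                       mass_curvature = c(0.4, 0.2, 0.4),
                       noise_sigma_ppm = 0.5,
                       detection_prob = 0.9,
                       n_decoys = 0L,
                       decoy_offset_ppm = c(10, 20),
                       decoy_coverage = 0.4,
                       background_peaks = 30L,
                       intensity_meanlog = log(1000), intensity_sdlog = 1,
                       polarity = "negative",
                       seed) {
  analyzer <- match.arg(analyzer)
  if (missing(seed)) stop("a seed is mandatory for the simulator", call. = FALSE)
  bad <- c(
    if (drift_amplitude_ppm < 0) "drift_amplitude_ppm must be >= 0",
    if (detection_prob < 0 || detection_prob > 1) "detection_prob must be in [0,1]",
    if (noise_sigma_ppm < 0) "noise_sigma_ppm must be >= 0",
    if (roi_fraction <= 0 || roi_fraction > 1) "roi_fraction must be in (0,1]"
  )
  if (length(bad)) stop("invalid simulation config: ",
                        paste(bad, collapse = "; "), call. = FALSE)
  structure(
    list(
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      roi_fraction = roi_fraction, analyzer = analyzer,
      reference_mzs = sort(reference_mzs),
      drift_amplitude_ppm = drift_amplitude_ppm,
      drift_period_pixels = drift_period_pixels,
      drift_phase = drift_phase,
      mass_curvature = mass_curvature,
      noise_sigma_ppm = noise_sigma_ppm,
      detection_prob = detection_prob,
      n_decoys = as.integer(n_decoys),
      decoy_offset_ppm = decoy_offset_ppm,
      decoy_coverage = decoy_coverage,
      background_peaks = as.integer(background_peaks),
      intensity_meanlog = intensity_meanlog,
      intensity_sdlog = intensity_sdlog,
      polarity = polarity,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Default planted reference ions
#'
#' Twenty lipid-like m/z values spanning the typical DESI negative-mode
#' acquisition range (fatty acids around 200-350, phospholipids 600-900).
#'
#' @return Numeric vector of m/z values.
#' @export
default_reference_mzs <- function() {
  c(227.2017, 253.2173, 255.2330, 269.2486, 279.2330, 281.2486, 283.2643,
    303.2330, 327.2330, 331.2643, 437.2670, 480.3090, 564.3300, 599.3200,
    673.4820, 699.4970, 744.5550, 788.5440, 834.5290, 885.5500)
}

#' Default held-out test ions
#'
#' Twenty lipid-like m/z values interleaved with [default_reference_mzs()]
#' but at least 0.15 Da away from every fitting reference, so that neither
#' the reference search window (up to 100 ppm) nor the test-mass window can
#' confuse the two sets.
#'
#' @return Numeric vector of m/z values.
#' @export
default_test_mzs <- function() {
  c(239.2380, 247.2420, 265.2540, 275.2010, 287.2380, 297.2800, 311.2950,
    319.2280, 341.3060, 365.3420, 413.3260, 459.2860, 507.3600, 540.3450,
    637.4710, 687.5450, 721.5030, 766.5390, 810.6010, 859.6210)
}

#' Pixel-order drift field in ppm
#'
#' Smooth sinusoidal drift over acquisition order, optionally modulated by a
#' quadratic polynomial in the scaled sqrt-mass (TOF). The modulation is
#' normalised to peak at 1 over the simulated mass range so that
#' `drift_amplitude_ppm` is the attained maximum absolute drift.
#'
#' @param config A [sim_config()].
#' @param pixel_index Integer vector of 0-based acquisition indices.
#' @param mz Vector of theoretical masses (recycled against `pixel_index`).
#' @return Drift in ppm, one value per (pixel, mass) pair.
#' @export
drift_field_ppm <- function(config, pixel_index, mz) {
  n_pix <- config$n_rows * config$n_cols
  period <- config$drift_period_pixels %||% (n_pix / 1.5)
  time_part <- sin(2 * pi * pixel_index / period + config$drift_phase)
  if (config$analyzer == "orbitrap") {
    return(config$drift_amplitude_ppm * time_part)
  }
  s <- sqrt(mz)
  rng <- sqrt(range(config$reference_mzs))
  z <- if (rng[2] > rng[1]) (s - rng[1]) / (rng[2] - rng[1]) else rep(1, length(s))
  w <- config$mass_curvature
  poly <- w[1] + w[2] * z + w[3] * z^2
  zg <- seq(0, 1, length.out = 512)
  norm <- max(abs(w[1] + w[2] * zg + w[3] * zg^2))
  config$drift_amplitude_ppm * time_part * poly / norm
}

#' Simulate an MSI dataset with planted drift
#'
#' Reference peaks are planted at their drifted positions with added ppm
#' noise and per-pixel Bernoulli detection; decoys are planted at fixed ppm
#' offsets from randomly chosen references over one contiguous block of ROI
#' pixels (interferents with a complementary spatial distribution);
#' off-sample pixels carry only random background peaks. Deterministic given
#' the config seed.
#'
#' @param config A [sim_config()].
#' @return A list with `dataset` ([msi_dataset()]), `roi` (0/1 matrix) and
#'   `truth`, a tibble of per (pixel, reference) ground truth: `mz_theo`,
#'   `drift_ppm`, `mz_drifted` (pre-noise), `mz_obs`, `detected`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, .simulate_dataset_impl(config))
}

.simulate_dataset_impl <- function(config) {
  nr <- config$n_rows; nc <- config$n_cols
  n_pix <- nr * nc
  # acquisition order: row-major raster scan (y rows, x columns)
  coords <- tibble::tibble(
    pixel_index = 0:(n_pix - 1),
    x = rep(seq_len(nc), times = nr),
    y = rep(seq_len(nr), each = nc)
  )
  roi_rows <- max(1L, round(config$roi_fraction * nr))
  row_lo <- (nr - roi_rows) %/% 2 + 1L
  roi <- matrix(0L, nr, nc)
  roi[row_lo:(row_lo + roi_rows - 1L), ] <- 1L
  on_roi <- roi[cbind(coords$y, coords$x)] == 1

  refs <- config$reference_mzs
  k <- length(refs)

  grid <- tidyr::crossing(pixel_index = coords$pixel_index[on_roi],
                          mz_theo = refs)
  grid$drift_ppm <- drift_field_ppm(config, grid$pixel_index, grid$mz_theo)
  grid$mz_drifted <- grid$mz_theo * (1 + grid$drift_ppm * 1e-6)
  noise <- rnorm(nrow(grid), 0, config$noise_sigma_ppm)
  grid$mz_obs <- grid$mz_theo * (1 + (grid$drift_ppm + noise) * 1e-6)
  grid$detected <- rbinom(nrow(grid), 1, config$detection_prob) == 1
  grid$intensity <- rlnorm(nrow(grid), config$intensity_meanlog,
                           config$intensity_sdlog)

  peaks <- grid[grid$detected, c("pixel_index", "mz_obs", "intensity")]
  names(peaks)[2] <- "mz"

  # decoy interferents: fixed ppm offset from a reference, detected over one
  # contiguous block of image columns -- a spatial region complementary to
  # the bulk tissue, which raster scanning interleaves across pixel order
  if (config$n_decoys > 0) {
    decoy_rows <- lapply(seq_len(config$n_decoys), function(d) {
      host <- refs[sample.int(length(refs), 1)]
      off <- runif(1, config$decoy_offset_ppm[1], config$decoy_offset_ppm[2]) *
        sample(c(-1, 1), 1)
      n_block_cols <- max(1L, round(config$decoy_coverage * nc))
      col_start <- sample.int(nc - n_block_cols + 1L, 1)
      in_block <- on_roi & coords$x >= col_start &
        coords$x < col_start + n_block_cols
      pix <- coords$pixel_index[in_block]
      decoy_theo <- host * (1 + off * 1e-6)
      dppm <- drift_field_ppm(config, pix, decoy_theo)
      nse <- rnorm(length(pix), 0, config$noise_sigma_ppm)
      tibble::tibble(
        pixel_index = pix,
        mz = decoy_theo * (1 + (dppm + nse) * 1e-6),
        intensity = rlnorm(length(pix), config$intensity_meanlog,
                           config$intensity_sdlog)
      )
    })
    peaks <- dplyr::bind_rows(peaks, dplyr::bind_rows(decoy_rows))
  }

  # off-sample pixels: random background peaks only
  off_pix <- coords$pixel_index[!on_roi]
  if (length(off_pix) > 0 && config$background_peaks > 0) {
    nb <- config$background_peaks
    bg <- tibble::tibble(
      pixel_index = rep(off_pix, each = nb),
      mz = runif(length(off_pix) * nb, min(refs) - 50, max(refs) + 50),
      intensity = rlnorm(length(off_pix) * nb, config$intensity_meanlog - 2,
                         config$intensity_sdlog)
    )
    peaks <- dplyr::bind_rows(peaks, bg)
  }

  dataset <- msi_dataset(peaks, coords, n_rows = nr, n_cols = nc,
                         polarity = config$polarity,
                         analyzer = config$analyzer)
  list(
    dataset = dataset, roi = roi,
    truth = grid[c("pixel_index", "mz_theo", "drift_ppm", "mz_drifted",
                   "mz_obs", "detected")]
  )
}

#' Score a recalibration against the simulation ground truth
#'
#' Looks up, for every detected planted reference peak, its recalibrated
#' position and summarises absolute ppm errors before and after. Because the
#' ground truth records each peak's noise-free drifted position, the
#' post-recalibration error is also decomposed into the systematic part
#' (what the calibration maps can control) and the irreducible per-peak
#' measurement noise: `err_after_systematic = err_after - noise_ppm` (exact
#' to first order in the noise, the map slope being ~1).
#'
#' @param truth Ground-truth tibble from [simulate_dataset()].
#' @param original,recalibrated The uncalibrated and recalibrated datasets.
#' @param subset_mzs Optional subset of planted theoretical masses to score
#'   (e.g. held-out test ions only).
#' @return A list with `per_reference` (tibble of per-reference median and
#'   95th-percentile absolute ppm errors before/after), `global` (same
#'   summaries pooled, plus `median_abs_after_systematic`), and `detail`.
#' @export
score_recalibration <- function(truth, original, recalibrated,
                                subset_mzs = NULL) {
  if (!identical(original$coords$pixel_index, recalibrated$coords$pixel_index)) {
    stop("pixel sets of the two datasets differ", call. = FALSE)
  }
  det <- truth[truth$detected, ]
  if (!is.null(subset_mzs)) {
    det <- det[det$mz_theo %in% subset_mzs, ]
  }
  # planted peaks are recovered by exact position match in the original data,
  # then mapped to the recalibrated spectrum by within-pixel rank
  orig_split <- split(original$peaks$mz,
                      factor(original$peaks$pixel_index,
                             levels = original$coords$pixel_index))
  recal_split <- split(recalibrated$peaks$mz,
                       factor(recalibrated$peaks$pixel_index,
                              levels = recalibrated$coords$pixel_index))
  pi <- match(det$pixel_index, original$coords$pixel_index)
  after <- vapply(seq_len(nrow(det)), function(j) {
    omz <- orig_split[[pi[j]]]
    r <- which.min(abs(omz - det$mz_obs[j]))
    recal_split[[pi[j]]][r]
  }, 0)
  det$err_before_ppm <- (det$mz_obs - det$mz_theo) / det$mz_theo * 1e6
  det$err_after_ppm <- (after - det$mz_theo) / det$mz_theo * 1e6
  det$noise_ppm <- (det$mz_obs - det$mz_drifted) / det$mz_theo * 1e6
  det$err_after_systematic_ppm <- det$err_after_ppm - det$noise_ppm
  q95 <- function(v) unname(quantile(abs(v), 0.95))
  per_ref <- det |>
    dplyr::group_by(.data$mz_theo) |>
    dplyr::summarise(
      median_abs_before = median(abs(.data$err_before_ppm)),
      median_abs_after = median(abs(.data$err_after_ppm)),
      q95_abs_before = q95(.data$err_before_ppm),
      q95_abs_after = q95(.data$err_after_ppm),
      .groups = "drop"
    )
  list(
    per_reference = per_ref,
    global = tibble::tibble(
      median_abs_before = median(abs(det$err_before_ppm)),
      median_abs_after = median(abs(det$err_after_ppm)),
      median_abs_after_systematic = median(abs(det$err_after_systematic_ppm)),
      q95_abs_before = q95(det$err_before_ppm),
      q95_abs_after = q95(det$err_after_ppm)
    ),
    detail = det
  )
}
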