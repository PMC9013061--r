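# Small in-code fixtures shared across the test files.

# A tiny dataset built by hand: `n` pixels on a 1 x n grid, given peak lists.
tiny_dataset <- function(peak_lists, polarity = "negative",
                         analyzer = "orbitrap") {
  n <- length(peak_lists)
  peaks <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    pl <- peak_lists[[i]]
    if (nrow(pl) == 0) return(NULL)
    tibble::tibble(pixel_index = i - 1L, mz = pl$mz, intensity = pl$intensity)
  }))
  if (is.null(peaks) || nrow(peaks) == 0) {
    peaks <- tibble::tibble(pixel_index = integer(), mz = numeric(),
                            intensity = numeric())
  }
  coords <- tibble::tibble(pixel_index = 0:(n - 1), x = seq_len(n), y = 1L)
  msi_dataset(peaks, coords, n_rows = 1, n_cols = n,
              polarity = polarity, analyzer = analyzer)
}

full_roi <- function(dataset) matrix(1L, dataset$n_rows, dataset$n_cols)

# Two-track fixture: one reference with a decoy interferent 15 ppm away over
# a complementary spatial block. `resolvable` switches between a small-drift
# Orbitrap-like setting and a large-drift TOF-like one.
two_track_config <- function(resolvable, seed) {
  sim_config(
    n_rows = 40, n_cols = 50, roi_fraction = 0.8,
    analyzer = if (resolvable) "orbitrap" else "tof",
    reference_mzs = 400.0,
    drift_amplitude_ppm = if (resolvable) 5 else 60,
    noise_sigma_ppm = if (resolvable) 0.5 else 3,
    detection_prob = 0.9,
    n_decoys = 1L, decoy_offset_ppm = c(15, 15), decoy_coverage = 0.4,
    background_peaks = 0L, seed = seed
  )
}

# Brute-force linear-scan reference search oracle.
linear_scan_search <- function(dataset, roi, mz, ppm) {
  lam <- ppm * mz * 1e-6
  roi_pix <- roi_pixel_indices(dataset, roi)
  rows <- list()
  for (p in roi_pix) {
    sp <- pixel_spectrum(dataset, p)
    hit <- which(sp$mz >= mz - lam & sp$mz <= mz + lam)
    for (j in hit) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        pixel_index = p, peak_index = j, mz_obs = sp$mz[j],
        intensity = sp$intensity[j]
      )
    }
  }
  dplyr::bind_rows(rows)
}
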