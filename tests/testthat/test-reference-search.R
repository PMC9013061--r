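test_that("adduct m/z values reproduce the standard fatty-acid references", {
  # palmitic acid [M-H]- and oleic acid [M-H]-
  expect_equal(adduct_mz(256.24023, "[M-H]-"), 255.2330, tolerance = 1e-4)
  expect_equal(adduct_mz(282.25588, "[M-H]-"), 281.2486, tolerance = 1e-4)
  expect_equal(adduct_mz(100, "[M+H]+"), 101.007276)
  expect_error(adduct_mz(0, "[M-H]-"))
  expect_error(adduct_mz(100, "[M-H]-", polarity = "positive"), "polarity")
  expect_error(adduct_mz(100, "[M+X]+"), "unknown adduct")
})

test_that("adduct expansion covers the polarity set and deduplicates", {
  db <- tibble::tibble(
    name = c("a", "b"), formula = c("X", "Y"),
    neutral_mass = c(256.24023, 256.24023), class = "fa"
  )
  neg <- expand_adducts(db, "negative")
  expect_equal(nrow(neg), 2)  # [M-H]- and [M+Cl]-, duplicates merged
  expect_true(all(grepl(";", neg$name)))
  pos <- expand_adducts(db, "positive")
  expect_equal(nrow(pos), 3)  # +H, +Na, +K
  expect_true(all(diff(pos$mz) > 0))
})

test_that("the ppm window is symmetric with half-width W*M*1e-6", {
  w <- ppm_window(303.2329, 20)
  lam <- 20 * 303.2329 * 1e-6
  expect_equal(lam, 0.006064658, tolerance = 1e-6)
  expect_equal(w, c(303.2329 - lam, 303.2329 + lam))
  expect_equal(ppm_window(1000, 100), c(999.9, 1000.1))
  expect_equal(ppm_window(500, 0), c(500, 500))
})

test_that("binary-search reference matching equals an exhaustive linear scan", {
  cfg <- sim_config(n_rows = 8, n_cols = 10, roi_fraction = 0.75,
                    reference_mzs = c(255.2330, 281.2486, 700.5),
                    drift_amplitude_ppm = 8, noise_sigma_ppm = 2,
                    detection_prob = 0.8, n_decoys = 2,
                    background_peaks = 10, seed = 41)
  sim <- simulate_dataset(cfg)
  for (mz in c(255.2330, 281.2486, 700.5)) {
    for (W in c(5, 20, 100)) {
      got <- search_reference(sim$dataset, sim$roi, mz, W)
      oracle <- linear_scan_search(sim$dataset, sim$roi, mz, W)
      expect_equal(nrow(got), nrow(oracle))
      if (nrow(got) > 0) {
        expect_equal(got$mz_obs, oracle$mz_obs)
        expect_equal(got$pixel_index, oracle$pixel_index)
        expect_equal(got$peak_index, oracle$peak_index)
      }
    }
  }
})

test_that("window boundaries are closed and off-ROI pixels are excluded", {
  M <- 303.2329; W <- 20
  lam <- W * M * 1e-6
  ds <- tiny_dataset(list(
    tibble::tibble(mz = c(M - lam, M + lam), intensity = c(1, 2)),  # both on edge
    tibble::tibble(mz = M, intensity = 3)
  ))
  roi <- matrix(c(1L, 0L), 1, 2)
  hits <- search_reference(ds, roi, M, W)
  expect_equal(nrow(hits), 2)            # closed interval keeps both edges
  expect_true(all(hits$pixel_index == 0))  # pixel 1 is off-ROI

  # both peaks of one pixel within the window are matched
  ds2 <- tiny_dataset(list(
    tibble::tibble(mz = c(303.2300, 303.2350), intensity = c(1, 1))
  ))
  expect_equal(nrow(search_reference(ds2, full_roi(ds2), M, W)), 2)

  # no ROI pixels -> empty table
  expect_equal(nrow(search_reference(ds, matrix(0L, 1, 2), M, W)), 0)
})

test_that("the coverage filter keeps references at >= 75% distinct pixels", {
  mk_table <- function(pixels) {
    t <- tibble::tibble(pixel_index = pixels, peak_index = 1L,
                        mz_obs = 300, intensity = 1)
    attr(t, "reference_mz") <- 300
    t
  }
  tabs <- list(
    covered74 = mk_table(0:73),
    covered75 = mk_table(0:74),
    duplicated = mk_table(rep(0:69, 2)),  # 140 matches but 70 pixels
    empty = mk_table(integer(0))
  )
  kept <- coverage_filter(tabs, n_roi = 100, min_frac = 0.75)
  expect_identical(names(kept), "covered75")
})
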