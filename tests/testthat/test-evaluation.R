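test_that("Delta-tilde is the median of per-pixel median paired differences", {
  mk <- function(px, before, after) {
    tibble::tibble(pixel_index = px, test_mz = 300,
                   err_before_ppm = before, err_after_ppm = after)
  }
  # after == before -> 0
  e0 <- mk(1:5, c(3, -2, 5, 1, -4), c(3, -2, 5, 1, -4))
  expect_equal(delta_statistic(e0)$delta, 0)

  # constant 10 -> 2 improvement everywhere -> 8
  e1 <- mk(1:6, rep(10, 6), rep(2, 6))
  expect_equal(delta_statistic(e1)$delta, 8)

  # three pixels with per-pixel medians {1, 2, 9} -> 2
  e2 <- tibble::tibble(
    pixel_index = c(1, 1, 2, 2, 3, 3), test_mz = 300,
    err_before_ppm = c(2, 2, 3, 3, 10, 10),
    err_after_ppm = c(1, 1, 1, 1, 1, 1)
  )
  expect_equal(delta_statistic(e2)$delta, 2)

  # permutation invariance over pixels
  set.seed(41)
  e3 <- mk(1:30, rnorm(30, 5), rnorm(30, 2))
  perm <- sample(30)
  e3p <- e3[perm, ]
  expect_equal(delta_statistic(e3)$delta, delta_statistic(e3p)$delta)
})

test_that("the bootstrap p-value respects its floor, ceiling and seed", {
  # all diffs positive: no sign contradiction possible -> floor 2/B
  r <- bootstrap_test(rep(5, 20), B = 500L, seed = 3)
  expect_equal(r$p_value, 2 / 500)

  # constant zero diffs -> p = 1
  expect_equal(bootstrap_test(rep(0, 20), B = 200L, seed = 3)$p_value, 1)

  # reproducible given a seed
  set.seed(42); d <- rnorm(40, 0.2)
  r1 <- bootstrap_test(d, B = 1000L, seed = 9)
  r2 <- bootstrap_test(d, B = 1000L, seed = 9)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$boot_medians, r2$boot_medians)

  expect_error(bootstrap_test(rnorm(5), B = 100L, seed = 1), "n >= 10")
})

test_that("BH adjustment matches the step-up closed form and is monotone", {
  # closed form: sort p, p_(i) * m / i, cumulative minimum from the top
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- rev(cummin(rev(p[o] * m / seq_len(m))))
    pmin(1, adj)[order(o)]
  }
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 4)), rep(1, 4))
  set.seed(43)
  for (i in 1:20) {
    p <- runif(sample(2:30, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    expect_true(all(adj <= 1))
  }
})

test_that("test-mass selection excludes fitting references and error outliers", {
  # synthetic dataset in which all planted ions carry a +4 ppm error and one
  # candidate sits 20 ppm off
  ions <- c(300.1, 400.2, 500.3, 600.4)
  cfg <- sim_config(n_rows = 5, n_cols = 8, roi_fraction = 1,
                    reference_mzs = ions, drift_amplitude_ppm = 4,
                    drift_period_pixels = 1e9,  # near-constant +4 ppm offset
                    drift_phase = pi / 2, noise_sigma_ppm = 0.2,
                    detection_prob = 1, background_peaks = 0, seed = 44)
  sim <- simulate_dataset(cfg)
  # candidate at 700.0 does not exist in the data; candidate 500.3001
  # collides with the fitting reference 500.3 and must be excluded upstream
  kept <- select_test_masses(
    candidates = c(300.1, 400.2, 500.30005, 600.4 * (1 + 20e-6)),
    dataset = sim$dataset, roi = sim$roi,
    fitting_refs = c(500.3), search_ppm = 20, window_ppm = 2.5
  )
  expect_true(all(c(300.1, 400.2) %in% kept))
  expect_false(any(abs(kept - 500.30005) < 1e-9))

  # single candidate: it is the mode, hence retained
  kept1 <- select_test_masses(300.1, sim$dataset, sim$roi,
                              fitting_refs = numeric(0),
                              search_ppm = 20)
  expect_equal(kept1, 300.1)
})

test_that("end-to-end evaluation pairs peaks across the calibration map", {
  ions <- c(300.1, 400.2, 500.3)
  cfg <- sim_config(n_rows = 5, n_cols = 8, roi_fraction = 1,
                    reference_mzs = ions, drift_amplitude_ppm = 5,
                    noise_sigma_ppm = 0.3, detection_prob = 1,
                    background_peaks = 0, seed = 45)
  sim <- simulate_dataset(cfg)
  # a fake perfect recalibration: move every planted peak to its theoretical
  truth <- sim$truth
  perfect <- sim$dataset
  key <- paste(truth$pixel_index, signif(truth$mz_obs, 12))
  idx <- match(paste(perfect$peaks$pixel_index, signif(perfect$peaks$mz, 12)), key)
  perfect$peaks$mz <- truth$mz_theo[idx]
  ev <- evaluate_recalibration(sim$dataset, perfect, sim$roi, ions,
                               search_ppm = 20, B = 1000L, seed = 2)
  expect_equal(ev$median_abs_after, 0)
  expect_gt(ev$delta, 0)
  expect_lt(ev$p_value, 0.05)
  expect_s3_class(glance(ev), "tbl_df")
  expect_equal(nrow(tidy(ev)), nrow(ev$errors))
})
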