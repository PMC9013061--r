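test_that("the common-error filter retains the dominant error mode", {
  mk <- function(err_ppm) {
    m0 <- c(250, 300, 400, 500, 600, 700, 800, 850, 880, 900)[seq_along(err_ppm)]
    tibble::tibble(mz_theo = m0, mz_pred = m0 * (1 + err_ppm * 1e-6))
  }
  # brute-force rule: mode of {5.0, 5.2, 4.9} cluster, -20 removed
  f <- filter_common_error(mk(c(5.0, 5.2, 4.9, -20)), band_ppm = 2.5)
  expect_equal(nrow(f), 3)
  expect_true(all(abs(f$error_ppm - 5) < 1))

  # all equal -> all retained
  expect_equal(nrow(filter_common_error(mk(rep(3, 5)), 2.5)), 5)

  # bimodal: exactly one mode retained, deterministically
  bim <- mk(c(rep(5, 5), rep(-5, 5)))
  f1 <- filter_common_error(bim, 2.5)
  f2 <- filter_common_error(bim, 2.5)
  expect_equal(nrow(f1), 5)
  expect_identical(f1$mz_theo, f2$mz_theo)
  expect_lte(diff(range(f1$error_ppm)), 1e-9)

  # fewer than 2 survivors -> unfiltered fallback with warning
  two <- mk(c(10, -10))
  expect_warning(f3 <- filter_common_error(two, 0.5), "unfiltered")
  expect_equal(nrow(f3), 2)
})

test_that("the Orbitrap linear model inverts planted shifts", {
  m0 <- seq(200, 900, length.out = 10)
  # identity recovery
  refs <- tibble::tibble(mz_theo = m0, mz_pred = m0)
  fit <- fit_orbitrap_model(refs)
  expect_equal(unname(fit$coefficients), c(0, 1), tolerance = 1e-9)

  # planted 5 ppm multiplicative shift: closed-form OLS says
  # beta0 = 0, beta1 = 1/(1 + 5e-6); residual error < 0.01 ppm
  shifted <- tibble::tibble(mz_theo = m0, mz_pred = m0 * (1 + 5e-6))
  fit2 <- fit_orbitrap_model(shifted)
  sp <- apply_model(fit2, tibble::tibble(mz = shifted$mz_pred, intensity = 1))
  expect_lt(max(abs(sp$mz - m0) / m0 * 1e6), 0.01)

  # n = p: two references interpolate exactly
  refs2 <- tibble::tibble(mz_theo = c(300, 600), mz_pred = c(300.001, 600.004))
  fit3 <- fit_orbitrap_model(refs2)
  pred <- fit3$coefficients[1] + fit3$coefficients[2] * refs2$mz_pred
  expect_equal(unname(pred), refs2$mz_theo, tolerance = 1e-10)

  expect_error(
    fit_orbitrap_model(tibble::tibble(mz_theo = c(1, 2), mz_pred = c(5, 5))),
    "degenerate"
  )
})

test_that("TOF BIC degree selection recovers the generating degree", {
  # data generated from a D=2 sqrt-domain polynomial with response noise:
  # BIC picks D = 2 in at least 90% of seeded repeats
  m0 <- seq(200, 900, length.out = 100)
  s0 <- sqrt(m0)
  picks <- withr::with_seed(31, vapply(1:100, function(i) {
    s_theo <- 1e-3 + (1 + 2e-4) * s0 + 3e-5 * s0^2 + rnorm(100, 0, 2e-5)
    refs <- tibble::tibble(mz_theo = s_theo^2, mz_pred = m0)
    fit_tof_model(refs)$degree
  }, 0L))
  expect_gte(mean(picks == 2), 0.9)

  # exact linear data: the BIC penalty picks D = 1
  refs_lin <- tibble::tibble(mz_theo = m0 * (1 + 2e-5), mz_pred = m0)
  expect_equal(fit_tof_model(refs_lin)$degree, 1L)

  # identity data recalibrates to itself
  refs_id <- tibble::tibble(mz_theo = m0, mz_pred = m0)
  fit_id <- fit_tof_model(refs_id)
  sp <- apply_model(fit_id, tibble::tibble(mz = m0, intensity = 1))
  expect_equal(sp$mz, m0, tolerance = 1e-9)
})

test_that("per-degree BIC follows the closed form n*log(RSS/n) + k*log(n)", {
  set.seed(32)
  m0 <- seq(250, 850, length.out = 12)
  refs <- tibble::tibble(mz_theo = m0,
                         mz_pred = m0 * (1 + rnorm(12, 10, 0.5) * 1e-6))
  fit <- fit_tof_model(refs)
  n <- 12
  for (D in as.integer(names(fit$bic))) {
    lmfit <- lm(sqrt(mz_theo) ~ poly(sqrt(mz_pred), D, raw = TRUE), refs)
    rss <- sum(residuals(lmfit)^2)
    expect_equal(unname(fit$bic[as.character(D)]),
                 n * log(rss / n) + (D + 1) * log(n), tolerance = 1e-6)
  }
})

test_that("model application maps masses and preserves everything else", {
  # identity model
  id <- structure(list(analyzer = "orbitrap", coefficients = c(0, 1),
                       degree = 1L), class = "pixel_recal_model")
  sp <- tibble::tibble(mz = c(100.5, 200.7), intensity = c(3, 4))
  expect_equal(apply_model(id, sp), sp, ignore_attr = TRUE)

  # direct arithmetic: beta = (0, 1 + 5e-6) applied to 600 -> 600.0030
  sh <- structure(list(analyzer = "orbitrap", coefficients = c(0, 1 + 5e-6),
                       degree = 1L), class = "pixel_recal_model")
  out <- apply_model(sh, tibble::tibble(mz = 600.0, intensity = 1))
  expect_equal(out$mz, 600.0030, tolerance = 1e-7)

  # empty spectrum passes through
  empty <- tibble::tibble(mz = numeric(), intensity = numeric())
  expect_equal(nrow(apply_model(id, empty)), 0)

  # intensity vector untouched, peak count conserved
  set.seed(33)
  spr <- tibble::tibble(mz = sort(runif(50, 100, 900)), intensity = rexp(50))
  outr <- apply_model(sh, spr)
  expect_equal(nrow(outr), 50)
  expect_equal(sort(outr$intensity), sort(spr$intensity))

  # TOF model with a negative sqrt-domain prediction leaves the peak alone
  bad <- structure(list(analyzer = "tof", coefficients = c(-100, 0.1),
                        degree = 1L), class = "pixel_recal_model")
  outb <- apply_model(bad, tibble::tibble(mz = 400, intensity = 1))
  expect_equal(outb$mz, 400)
  expect_false(attr(outb, "corrected"))
})

test_that("dataset recalibration is near-identity when predictions are exact", {
  cfg <- sim_config(n_rows = 6, n_cols = 8, roi_fraction = 1,
                    reference_mzs = seq(300, 800, length.out = 6),
                    drift_amplitude_ppm = 0, noise_sigma_ppm = 0,
                    detection_prob = 1, background_peaks = 0, seed = 35)
  sim <- simulate_dataset(cfg)
  trends <- lapply(seq(300, 800, length.out = 6), function(m) {
    structure(list(
      reference_mz = m,
      predictions = tibble::tibble(pixel_index = 0:47, mz_pred = m)
    ), class = "drift_trend")
  })
  out <- recalibrate_pixels(sim$dataset, sim$roi, trends, recal_config())
  rel <- abs(out$dataset$peaks$mz - sim$dataset$peaks$mz) / sim$dataset$peaks$mz
  expect_lt(max(rel), 1e-9)
  expect_true(all(out$models$fitted))
  expect_equal(out$models$degree, rep(1L, 48))
})
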