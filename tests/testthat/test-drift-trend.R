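test_that("the MAD consistency factor equals 1.4826 to five significant figures", {
  expect_equal(signif(mad_consistency_factor(), 5), 1.4826)
})

test_that("the ridge spline reproduces a line and tracks a noisy sine", {
  x <- seq(0, 1000, length.out = 200)
  line <- tibble::tibble(x = x, y = 2 + 0.001 * x)
  sp <- fit_ridge_spline(line)
  expect_equal(predict(sp, x), line$y, tolerance = 1e-6)

  set.seed(21)
  true_y <- 500 + 0.01 * sin(2 * pi * x / 700)
  noisy <- tibble::tibble(x = x, y = true_y + rnorm(200, 0, 0.001))
  sp2 <- fit_ridge_spline(noisy)
  rmse <- sqrt(mean((predict(sp2, x) - true_y)^2))
  expect_lt(rmse, 0.001)

  expect_error(fit_ridge_spline(line[1:4, ]), "at least 5")
})

test_that("outlier flagging equals brute-force application of the 2-mad rule", {
  set.seed(22)
  x <- seq(0, 500, length.out = 120)
  base <- tibble::tibble(x = x, y = 400 + 0.002 * sin(x / 80))
  sp <- fit_ridge_spline(base)
  for (i in 1:25) {
    n <- sample(20:80, 1)
    px <- sort(sample(0:500, n))
    mz <- 400 + 0.002 * sin(px / 80) + rnorm(n, 0, 2e-4) +
      ifelse(runif(n) < 0.1, 0.004, 0)   # occasional gross outliers
    matches <- tibble::tibble(pixel_index = px, peak_index = 1L,
                              mz_obs = mz, intensity = 1)
    attr(matches, "reference_mz") <- 400
    d <- flag_outliers(matches, sp)
    # independent brute force: r, mad = 1.4826 * median(r), rule r >= 2*mad
    r <- abs(mz - predict(sp, px))
    mad_bf <- 1.4826021 * median(r)
    inlier_bf <- if (mad_bf == 0) r == 0 else r < 2 * mad_bf
    expect_identical(d$inlier, inlier_bf)
    expect_equal(attr(d, "mad_r"), mad(r, center = 0))
  }
})

test_that("degenerate residual patterns follow the documented conventions", {
  x <- seq(0, 100, length.out = 50)
  sp <- fit_ridge_spline(tibble::tibble(x = x, y = rep(500, 50)))
  # all points exactly on the spline: no outliers, dispersion 0
  m0 <- tibble::tibble(pixel_index = x, peak_index = 1L,
                       mz_obs = rep(500, 50), intensity = 1)
  attr(m0, "reference_mz") <- 500
  d0 <- flag_outliers(m0, sp)
  expect_true(all(d0$inlier))
  expect_equal(attr(d0, "max_dispersion_ppm"), 0)

  # residuals {0,...,0,big}: mad = 0, only the deviant point is flagged
  m1 <- m0
  m1$mz_obs[50] <- 500.02
  d1 <- flag_outliers(m1, sp)
  expect_equal(sum(!d1$inlier), 1)
  expect_false(d1$inlier[50])
})

test_that("reference acceptance applies both coverage and dispersion rules", {
  mk_diag <- function(n_pix, disp) {
    d <- tibble::tibble(pixel_index = seq_len(n_pix), inlier = TRUE)
    attr(d, "max_dispersion_ppm") <- disp
    d
  }
  expect_true(accept_reference(mk_diag(76, 9), n_roi = 100))
  expect_false(accept_reference(mk_diag(76, 11), n_roi = 100))
  expect_false(accept_reference(mk_diag(74, 9), n_roi = 100))
  expect_true(accept_reference(mk_diag(75, 10), n_roi = 100))  # boundaries inclusive
  # monotone: raising dispersion never turns a reject into an accept
  for (d1 in c(2, 6, 9, 11, 15)) {
    for (d2 in c(2, 6, 9, 11, 15)) {
      if (d2 >= d1) {
        a1 <- accept_reference(mk_diag(80, d1), 100)
        a2 <- accept_reference(mk_diag(80, d2), 100)
        expect_true(a1 || !a2)
      }
    }
  }
})

test_that("the GAM trend recovers planted smooth drift within the noise", {
  set.seed(23)
  n <- 1500
  px <- sort(sample(0:1999, n))
  M <- 500
  drift_ppm <- 10 * sin(2 * pi * px / 1400)
  mz <- M * (1 + (drift_ppm + rnorm(n, 0, 1)) * 1e-6)
  d <- tibble::tibble(pixel_index = px, mz_obs = mz, inlier = TRUE)
  attr(d, "reference_mz") <- M
  trend <- fit_gam_trend(d, roi_pixels = 0:1999)
  truth <- M * (1 + 10 * sin(2 * pi * (0:1999) / 1400) * 1e-6)
  rms_ppm <- sqrt(mean(((trend$predictions$mz_pred - truth) / M * 1e6)^2))
  expect_lt(rms_ppm, 1)
  expect_true(all(is.finite(trend$predictions$mz_pred)))  # includes unmatched pixels

  # drift-free limit: predictions within 2 SE of the constant
  set.seed(24)
  mz0 <- M * (1 + rnorm(n, 0, 0.5) * 1e-6)
  d0 <- tibble::tibble(pixel_index = px, mz_obs = mz0, inlier = TRUE)
  attr(d0, "reference_mz") <- M
  trend0 <- fit_gam_trend(d0, roi_pixels = 0:1999)
  se_ppm <- 0.5 / sqrt(n) * 1e6 / 1e6
  dev_ppm <- abs(trend0$predictions$mz_pred - M) / M * 1e6
  expect_lt(median(dev_ppm), 0.2)

  # broom-style accessors
  expect_s3_class(tidy(trend), "tbl_df")
  expect_equal(nrow(glance(trend)), 1)
})

test_that("penalty selection uses the 11-value GCV grid", {
  set.seed(25)
  px <- 0:400
  d <- tibble::tibble(pixel_index = px,
                      mz_obs = 300 + rnorm(401, 0, 1e-4), inlier = TRUE)
  attr(d, "reference_mz") <- 300
  trend <- fit_gam_trend(d, roi_pixels = px)
  expect_length(trend$gcv, 11)
  expect_true(trend$sp %in% 10^seq(-3, 3, length.out = 11))
  expect_equal(trend$gcv[trend$sp_grid == trend$sp], min(trend$gcv))
})
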