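test_that("imzML round-trip preserves spectra, coordinates and metadata", {
  cfg <- sim_config(n_rows = 4, n_cols = 5, roi_fraction = 1,
                    reference_mzs = c(300.1, 400.2, 500.3),
                    drift_amplitude_ppm = 3, noise_sigma_ppm = 1,
                    detection_prob = 1, background_peaks = 0, seed = 5)
  ds <- simulate_dataset(cfg)$dataset
  path <- file.path(tempdir(), "roundtrip")
  write_imzml(ds, path)
  ds2 <- read_imzml(paste0(path, ".imzML"))

  expect_identical(ds2$peaks$mz, ds$peaks$mz)  # 64-bit storage is bitwise
  expect_equal(ds2$peaks$intensity, ds$peaks$intensity, tolerance = 1e-6)
  expect_identical(ds2$coords, ds$coords)
  expect_identical(ds2$polarity, ds$polarity)
  expect_identical(ds2$analyzer, ds$analyzer)
  expect_identical(ds2$n_rows, ds$n_rows)
})

test_that("pixels with empty spectra survive the round trip", {
  ds <- tiny_dataset(list(
    tibble::tibble(mz = c(100.5, 200.25, 300.125), intensity = c(1, 2, 3)),
    tibble::tibble(mz = numeric(), intensity = numeric()),
    tibble::tibble(mz = 150.75, intensity = 9)
  ))
  path <- file.path(tempdir(), "empties")
  write_imzml(ds, path)
  ds2 <- read_imzml(paste0(path, ".imzML"))
  expect_equal(n_pixels(ds2), 3)
  expect_equal(nrow(pixel_spectrum(ds2, 1)), 0)
  expect_identical(pixel_spectrum(ds2, 2)$mz, 150.75)
})

test_that("a spectrum stored with unsorted masses is returned sorted", {
  ds <- tiny_dataset(list(
    tibble::tibble(mz = c(100.0, 200.0, 300.0), intensity = c(1, 2, 3))
  ))
  path <- file.path(tempdir(), "unsorted")
  write_imzml(ds, path)
  # rewrite the ibd m/z array in scrambled order
  con <- file(paste0(path, ".ibd"), open = "r+b")
  seek(con, 16, rw = "write")
  writeBin(c(300.0, 100.0, 200.0), con, size = 8, endian = "little")
  seek(con, 16 + 24, rw = "write")
  writeBin(c(3, 1, 2), con, size = 4, endian = "little")
  close(con)
  ds2 <- read_imzml(paste0(path, ".imzML"))
  sp <- pixel_spectrum(ds2, 0)
  # oracle: explicit sort of the scrambled arrays
  ord <- order(c(300, 100, 200))
  expect_equal(sp$mz, c(300, 100, 200)[ord])
  expect_equal(sp$intensity, c(3, 1, 2)[ord], tolerance = 1e-7)
})

test_that("the writer's imzML is read identically by pyimzml", {
  ds <- tiny_dataset(list(
    tibble::tibble(mz = c(255.2330, 281.2486), intensity = c(10, 20)),
    tibble::tibble(mz = 303.2329, intensity = 5)
  ))
  path <- file.path(tempdir(), "pyoracle")
  write_imzml(ds, path)
  script <- sprintf(
    paste0("from pyimzml.ImzMLParser import ImzMLParser\n",
           "p = ImzMLParser('%s.imzML')\n",
           "mz, it = p.getspectrum(0)\n",
           "print(len(p.coordinates)); print(repr(list(mz))); print(p.coordinates[0][:2])\n"),
    path
  )
  out <- tryCatch(
    system2("python", "-", input = script, stdout = TRUE, stderr = TRUE),
    warning = function(w) NULL, error = function(e) NULL
  )
  expect_false(is.null(out))
  expect_equal(out[1], "2")
  expect_match(out[2], "255.233")
  expect_match(out[2], "281.2486")
  expect_equal(out[3], "(1, 1)")
})

test_that("invalid inputs are rejected with informative errors", {
  expect_error(read_imzml(file.path(tempdir(), "nope.imzML")), "not found")
  # missing ibd companion
  ds <- tiny_dataset(list(tibble::tibble(mz = 100, intensity = 1)))
  path <- file.path(tempdir(), "orphan")
  write_imzml(ds, path)
  file.remove(paste0(path, ".ibd"))
  expect_error(read_imzml(paste0(path, ".imzML")), "ibd")
  # negative intensity violates the container invariant
  expect_error(
    tiny_dataset(list(tibble::tibble(mz = 100, intensity = -1))),
    "non-negative"
  )
})

test_that("ROI mask CSV reading validates dimensions and binary values", {
  p <- file.path(tempdir(), "roi2x2.csv")
  writeLines(c("1,0", "0,1"), p)
  roi <- read_roi_mask(p, 2, 2)
  expect_identical(sum(roi), 2L)

  writeLines(c("0,0", "0,0"), p)
  expect_identical(sum(read_roi_mask(p, 2, 2)), 0L)

  writeLines(c("1,2", "0,1"), p)
  expect_error(read_roi_mask(p, 2, 2), "row 1, column 2")
  writeLines(c("1,0,1", "0,1,0"), p)
  expect_error(read_roi_mask(p, 2, 2), "columns")

  # write/read identity
  m <- matrix(c(1L, 0L, 0L, 1L, 1L, 0L), 2, 3)
  p2 <- file.path(tempdir(), "roi_rt.csv")
  write_roi_mask(m, p2)
  expect_identical(read_roi_mask(p2, 2, 3), m)
})

test_that("an all-zero ROI mask is refused downstream", {
  ds <- tiny_dataset(list(tibble::tibble(mz = 100, intensity = 1)))
  roi <- matrix(0L, 1, 1)
  expect_error(recalibrate_msi(ds, roi, 100.0), "no pixels")
})

test_that("an explicit pixel order vector reorders acquisition indices", {
  ds <- tiny_dataset(list(
    tibble::tibble(mz = 100, intensity = 1),
    tibble::tibble(mz = 200, intensity = 2)
  ))
  path <- file.path(tempdir(), "order")
  write_imzml(ds, path)
  ds2 <- read_imzml(paste0(path, ".imzML"), pixel_order = c(2L, 1L))
  expect_equal(ds2$peaks$mz[ds2$peaks$pixel_index == 0], 200)
})
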