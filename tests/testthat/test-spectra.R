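toy_long_file <- function(path) {
  writeLines(c(
    "# modality: emission",
    "# axis_kind: wavelength_nm",
    "# sample_id: toy",
    "axis,intensity,time_h,replicate",
    "470,1.5,0,1",
    "480,2.5,0,1",
    "490,2.0,0,1"
  ), path)
  path
}

test_that("long and wide dialects parse into validated spectra", {
  path <- withr::local_tempfile(fileext = ".csv")
  toy_long_file(path)
  s <- read_spectra(path, "long")
  expect_equal(nrow(s), 3)
  expect_equal(s$axis, c(470, 480, 490))
  expect_equal(s$sample_id[1], "toy")

  wide <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "# modality: emission",
    "# axis_kind: wavelength_nm",
    "# sample_id: toy",
    "# replicate: 2",
    "axis,0,24",
    "470,1,4",
    "480,2,5",
    "490,3,6"
  ), wide)
  sw <- read_spectra(wide, "wide")
  expect_equal(sort(unique(sw$time_h)), c(0, 24))
  expect_equal(nrow(sw), 6)
  expect_equal(unique(sw$replicate), 2L)
  # both time points share one axis
  expect_equal(sw$axis[sw$time_h == 0], sw$axis[sw$time_h == 24])
})

test_that("malformed spectra files and tables are rejected with context", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# modality: emission", "axis,intensity", "1,2"), path)
  expect_error(read_spectra(path), "missing '# axis_kind")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "# modality: emission", "# axis_kind: wavelength_nm", "# sample_id: t",
    "axis,intensity,time_h", "470,1,0"
  ), path2)
  expect_error(read_spectra(path2, "long"), "replicate")

  # non-monotone axis caught by the validator
  bad <- tibble::tibble(
    sample_id = "x", modality = "emission", axis_kind = "wavelength_nm",
    replicate = 1L, time_h = 0, axis = c(1, 3, 2), intensity = c(1, 1, 1)
  )
  expect_error(as_spectra(bad), "not strictly monotone")
})

test_that("spectra survive a write/read round trip bit-exactly", {
  s <- spectrum(seq(400, 500, 5), dnorm(seq(400, 500, 5), 477.3, 13.7),
                sample_id = "rt", time_h = 2.5, replicate = 1L)
  s2 <- spectrum(seq(400, 500, 5), sqrt(seq(400, 500, 5)),
                 sample_id = "rt", time_h = 7.5, replicate = 2L)
  both <- dplyr::bind_rows(s, s2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra(both, path, "long")
  back <- read_spectra(path, "long")
  expect_identical(back$intensity, both$intensity)
  expect_identical(back$axis, both$axis)
  expect_identical(back$time_h, both$time_h)

  wpath <- withr::local_tempfile(fileext = ".csv")
  write_spectra(dplyr::bind_rows(
    spectrum(1:5, rnorm(5), time_h = 0),
    spectrum(1:5, rnorm(5), time_h = 24)
  ), wpath, "wide")
  wback <- read_spectra(wpath, "wide")
  expect_equal(nrow(wback), 10)
})

test_that("band_average matches brute force and simple closed forms", {
  # constant spectrum
  s <- spectrum(400:500, rep(3.25, 101))
  expect_equal(band_average(s, 475, 485)$value, 3.25)

  # linear ramp over a symmetric uniformly spaced window: value at centre
  ramp <- spectrum(400:500, 2 * (400:500) - 100)
  expect_equal(band_average(ramp, 475, 485)$value, 2 * 480 - 100)

  # brute-force index scan on a synthetic ThT-like peak
  withr::with_seed(1, {
    y <- 50 * exp(-0.5 * ((400:500 - 481) / 12)^2) + rnorm(101)
  })
  tht <- spectrum(400:500, y)
  idx <- which(400:500 >= 475 & 400:500 <= 485)
  expect_equal(band_average(tht, 475, 485)$value, mean(y[idx]))

  expect_error(band_average(s, 600, 610), "no axis points")
  expect_error(band_average(s, 485, 475), "smaller than")
})

test_that("band_average is linear in the spectrum", {
  x <- 400:460
  s1 <- spectrum(x, sin(x / 10))
  s2 <- spectrum(x, cos(x / 7))
  comb <- spectrum(x, 2.5 * sin(x / 10) - 1.5 * cos(x / 7))
  expect_equal(
    band_average(comb, 410, 450)$value,
    2.5 * band_average(s1, 410, 450)$value -
      1.5 * band_average(s2, 410, 450)$value
  )
})

test_that("savitzky_golay reproduces the classical quadratic filter", {
  # impulse response: central 13 outputs are the quadratic LS coefficients
  n <- 41
  y <- rep(0, n); y[(n + 1) / 2] <- 1
  s <- spectrum(1:n, y)
  sm <- savitzky_golay(s, 13, 2)
  centre <- (n + 1) / 2
  got <- sm$intensity[(centre - 6):(centre + 6)]
  want <- c(-11, 0, 9, 16, 21, 24, 25, 24, 21, 16, 9, 0, -11) / 143
  expect_equal(got, want, tolerance = 1e-12)

  # independently solved local least squares agrees on interior points
  withr::with_seed(3, yr <- rnorm(n))
  smr <- savitzky_golay(spectrum(1:n, yr), 13, 2)
  orc <- oracle_sg_fit(yr, 13, 2)
  interior <- 7:(n - 6)
  expect_equal(smr$intensity[interior], orc[interior], tolerance = 1e-10)
})

test_that("savitzky_golay fixes polynomials up to its order on the interior", {
  x <- seq(0, 4, by = 0.1)
  y <- 1.5 - 2 * x + 0.75 * x^2
  sm <- savitzky_golay(spectrum(x, y), 13, 2)
  interior <- 7:(length(x) - 6)
  expect_equal(sm$intensity[interior], y[interior], tolerance = 1e-10)

  # constant spectra are unchanged everywhere (reflect padding included)
  smc <- savitzky_golay(spectrum(x, rep(2, length(x))), 13, 2)
  expect_equal(smc$intensity, rep(2, length(x)))

  # smoothing commutes with adding a quadratic (interior points)
  withr::with_seed(9, noise <- rnorm(length(x)))
  a <- savitzky_golay(spectrum(x, noise + y), 13, 2)$intensity
  b <- savitzky_golay(spectrum(x, noise), 13, 2)$intensity + y
  expect_equal(a[interior], b[interior], tolerance = 1e-10)

  expect_error(savitzky_golay(spectrum(c(1, 2, 4, 6:20), rnorm(18))),
               "not uniformly spaced")
})

test_that("combine_spectra handles shared and mismatched grids", {
  x <- seq(200, 400, 2)
  s <- spectrum(x, sin(x / 30) + 2)
  z <- spectrum(x, rep(0, length(x)))

  self_cancel <- combine_spectra(s, s, 1, -1)
  expect_true(all(self_cancel$intensity == 0))

  doubled <- combine_spectra(s, z, 2, 1)
  expect_equal(doubled$intensity, 2 * s$intensity)

  # mismatched grids: agree with a dense-grid interpolation oracle
  a <- spectrum(seq(200, 300, 3), sin(seq(200, 300, 3) / 20))
  b <- spectrum(seq(210, 310, 4), cos(seq(210, 310, 4) / 25))
  got <- combine_spectra(a, b, 1.5, -0.5)
  dense <- sort(unique(c(a$axis, b$axis, seq(210, 300, 0.5))))
  oracle <- 1.5 * approx(a$axis, a$intensity, dense)$y -
    0.5 * approx(b$axis, b$intensity, dense)$y
  oracle_at_got <- approx(dense, oracle, got$axis)$y
  expect_equal(got$intensity, oracle_at_got, tolerance = 1e-6)

  disjoint <- spectrum(seq(500, 600, 5), rnorm(21))
  expect_error(combine_spectra(a, disjoint), "do not overlap")
  ftir <- spectrum(seq(1600, 1700, 2), rnorm(51), axis_kind = "wavenumber_cm1")
  expect_error(combine_spectra(a, ftir), "different axis kinds")
})
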