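emission_axis <- seq(250, 350, by = 1)

emission_spectrum <- function(y, time_h = 10, sample_id = "pep",
                              replicate = 1L) {
  spectrum(emission_axis, y, sample_id = sample_id, modality = "emission",
           time_h = time_h, replicate = replicate)
}

test_that("ret_difference vanishes bitwise under the symmetric additivity null", {
  withr::with_seed(2, y <- 40 * dnorm(emission_axis, 287, 10) + runif(101))
  a <- emission_spectrum(y, sample_id = "A")
  b <- emission_spectrum(y, sample_id = "B")
  mix <- emission_spectrum(y, sample_id = "A+B") # (y + y) / 2
  d <- ret_difference(a, b, mix, time_h = 10)
  expect_identical(d$intensity, rep(0, length(emission_axis)))
})

test_that("ret_difference is linear and recovers pure-mixture signal", {
  withr::with_seed(4, {
    ya <- 30 * dnorm(emission_axis, 287, 10)
    yb <- 25 * dnorm(emission_axis, 310, 12)
  })
  # additive non-interacting pair: F_mix = (F_A + F_B) / 2
  a <- emission_spectrum(ya, sample_id = "A")
  b <- emission_spectrum(yb, sample_id = "B")
  mix <- emission_spectrum((ya + yb) / 2, sample_id = "A+B")
  d <- ret_difference(a, b, mix, time_h = 10)
  expect_lt(max(abs(d$intensity)), 1e-12 * max(ya))

  # zero individuals: difference is twice the mixture (no smoothing)
  z <- emission_spectrum(rep(0, 101))
  m <- emission_spectrum(ya)
  d2 <- ret_difference(z, z, m, time_h = 10, sg_points = 0)
  expect_equal(d2$intensity, 2 * ya)

  # time matching outside tolerance errors
  late <- emission_spectrum(ya, time_h = 12)
  expect_error(ret_difference(late, b, mix, time_h = 10), "within 0.5 h")
})

test_that("ret_metrics averages the donor and acceptor windows", {
  y <- ifelse(emission_axis >= 300 & emission_axis <= 320, 1,
              ifelse(emission_axis >= 270 & emission_axis <= 290, -1, 0))
  d <- emission_spectrum(y)
  m <- ret_metrics(d)
  expect_equal(m$dF_phe, -1)
  expect_equal(m$dF_tyr, 1)
  z <- ret_metrics(emission_spectrum(rep(0, 101)))
  expect_equal(c(z$dF_phe, z$dF_tyr), c(0, 0))
})

test_that("detect_ret applies the sign rule and is monotone in the floor", {
  m <- tibble::tibble(dF_phe = c(-5, 2, -5), dF_tyr = c(3, 3, -1))
  got <- detect_ret(m)
  expect_equal(got$ret, c(TRUE, FALSE, FALSE))
  expect_equal(got$margin[1], 3)

  # raising the floor can only turn calls off
  floors <- c(0, 1, 2.5, 3, 5)
  calls <- vapply(floors, function(f) detect_ret(m, f)$ret[1], logical(1))
  expect_true(all(diff(as.integer(calls)) <= 0))
  expect_error(detect_ret(m, -1), "non-negative")
})

test_that("forster_efficiency satisfies its closed-form identities", {
  expect_identical(forster_efficiency(13.5), 0.5)
  expect_identical(forster_efficiency(0), 1)
  expect_equal(forster_efficiency(27), 1 / 65, tolerance = 1e-12)
  r <- seq(0, 60, by = 0.5)
  expect_true(all(diff(forster_efficiency(r)) < 0))
  # scale-free identity E(R0 x) (1 + x^6) = 1
  x <- c(0.2, 0.7, 1, 1.9, 3.4)
  expect_equal(forster_efficiency(13.5 * x) * (1 + x^6), rep(1, 5),
               tolerance = 1e-12)
  expect_error(forster_efficiency(-1), "non-negative")
  expect_error(forster_efficiency(5, r0 = 0), "positive")
})

test_that("an interacting pair shows donor quenching and acceptor gain", {
  pair <- simulate_emission_pair(
    truth = mixture_truth(efficiency = interaction_profile()),
    seed = 8
  )
  m <- ret_metrics(ret_difference(pair$f_a, pair$f_b, pair$f_mix, time_h = 20))
  expect_lt(m$dF_phe, 0)
  expect_gt(m$dF_tyr, 0)
  expect_true(detect_ret(m)$ret)
})

test_that("constant-efficiency bookkeeping matches the closed form", {
  obs <- observation_model(noise_sd = list(tht = 0, scattering = 0,
                                           emission = 0, ftir = 0),
                           replicate_cv = 0, quench_drift_amplitude = 0)
  e_const <- 0.5
  pair <- simulate_emission_pair(
    truth = mixture_truth(efficiency = function(t) rep(e_const, length(t))),
    obs = obs, a_phe = 100, a_tyr = 0, b_phe = 20, b_tyr = 80,
    times = c(1, 10), replicates = 1, seed = 1
  )
  d <- ret_difference(pair$f_a, pair$f_b, pair$f_mix, time_h = 10,
                      sg_points = 0)
  m <- ret_metrics(d)
  # pointwise bookkeeping: D(l) = E (a_phe + b_phe) [yield g_tyr(l) - g_phe(l)]
  band <- function(centre, fwhm) {
    exp(-0.5 * ((emission_axis - centre) / (fwhm / (2 * sqrt(2 * log(2)))))^2)
  }
  avg <- function(y, lo, hi) {
    band_average(emission_spectrum(y), lo, hi)$value
  }
  g_phe <- band(obs$phe_centre, obs$phe_fwhm)
  g_tyr <- band(obs$tyr_centre, obs$tyr_fwhm)
  expected <- function(lo, hi) {
    e_const * 120 * (obs$acceptor_yield * avg(g_tyr, lo, hi) -
                       avg(g_phe, lo, hi))
  }
  expect_equal(m$dF_phe, expected(270, 290), tolerance = 1e-9)
  expect_equal(m$dF_tyr, expected(300, 320), tolerance = 1e-9)
  expect_gt(m$dF_tyr, 0)
})

test_that("ret_noise_floor scales with baseline spread", {
  m <- tibble::tibble(time_h = c(1, 1, 2, 2, 20, 20),
                      dF_phe = c(-1, 1, -2, 2, -30, -28),
                      dF_tyr = c(0.5, -0.5, 1, -1, 20, 22))
  fl <- ret_noise_floor(m, baseline_t_max = 2)
  expect_equal(fl, 3 * sd(c(-1, 1, -2, 2, 0.5, -0.5, 1, -1)))
  expect_error(ret_noise_floor(m[5:6, ], baseline_t_max = 2), "baseline")
})
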