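test_that("Finke-Watzky closed form honours its boundary behaviour", {
  p <- kinetic_params(k_n = 0.02, k_e = 0.01, a0 = 35,
                      fibril_fraction_max = 0.8)
  curve <- simulate_aggregation(c(0, 5, 1e5), p)
  expect_equal(curve$fibril_uM[1], 0, tolerance = 1e-12)
  expect_equal(curve$fibril_uM[3], 0.8 * 35, tolerance = 1e-6)
  expect_true(all(diff(curve$aggregate_uM) > 0))
})

test_that("mass balance holds at every time point", {
  p <- kinetic_params(k_n = 0.03, k_e = 0.02, a0 = 50,
                      fibril_fraction_max = 0.7)
  curve <- simulate_aggregation(seq(0, 100, 0.5), p)
  total <- curve$fibril_uM + curve$amorphous_uM + curve$monomer_uM
  expect_lt(max(abs(total - 50)), 1e-9)
})

test_that("generators are bit-reproducible and seed-sensitive only in noise", {
  curve <- simulate_aggregation(c(0, 8, 24), kinetic_params())
  s1 <- simulate_tht_series(curve, seed = 7)
  s2 <- simulate_tht_series(curve, seed = 7)
  expect_identical(s1, s2)
  s3 <- simulate_tht_series(curve, seed = 8)
  expect_false(identical(s1$intensity, s3$intensity))

  # noiseless generation is seed-independent: ground truth untouched
  quiet <- observation_model(noise_sd = list(tht = 0, scattering = 0,
                                             emission = 0, ftir = 0),
                             replicate_cv = 0)
  expect_identical(simulate_tht_series(curve, quiet, seed = 1),
                   simulate_tht_series(curve, quiet, seed = 99))
})

test_that("zero binding capacity gives flat zero spectra", {
  curve <- simulate_aggregation(c(0, 24), kinetic_params())
  obs <- observation_model(tht_binding_capacity = 0,
                           noise_sd = list(tht = 0, scattering = 0,
                                           emission = 0, ftir = 0),
                           replicate_cv = 0)
  s <- simulate_tht_series(curve, obs)
  expect_true(all(s$intensity == 0))
})

test_that("noiseless ThT series reproduce the binding-capacity curve", {
  curve <- simulate_aggregation(c(0, 4, 8, 16, 32), kinetic_params())
  obs <- observation_model(noise_sd = list(tht = 0, scattering = 0,
                                           emission = 0, ftir = 0),
                           replicate_cv = 0)
  tc <- tht_timecourse(simulate_tht_series(curve, obs, replicates = 1))
  # proportional to capacity x fibril mass, shape factor from the band
  nz <- curve$fibril_uM > 0
  ratio <- tc$value[nz] / (obs$tht_binding_capacity * curve$fibril_uM[nz])
  expect_lt(diff(range(ratio)), 1e-10)
  expect_true(all(ratio > 0.5 & ratio < 1))
})

test_that("time-course noise follows window-averaging sampling theory", {
  curve <- simulate_aggregation(24, kinetic_params())
  obs <- observation_model(tht_binding_capacity = 0,
                           noise_sd = list(tht = 2, scattering = 0,
                                           emission = 0, ftir = 0),
                           replicate_cv = 0)
  s <- simulate_tht_series(curve, obs, replicates = 100, seed = 12)
  vals <- tht_timecourse(s)$value
  n_win <- sum(450:520 >= 475 & 450:520 <= 485)
  expect_lt(abs(sd(vals) - 2 / sqrt(n_win)) / (2 / sqrt(n_win)), 0.2)
})

test_that("generated spectra files parse back through read_spectra", {
  curve <- simulate_aggregation(c(0, 16, 32), kinetic_params())
  s <- simulate_tht_series(curve, replicates = 2, seed = 3,
                           sample_id = "roundtrip")
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra(s, path, "long")
  expect_no_warning(back <- read_spectra(path, "long"))
  expect_identical(back$intensity, s$intensity)
})

test_that("mixture generator recovers null and complete inhibition", {
  run_ip <- function(truth, seed) {
    sim <- simulate_mixture(truth = truth, seed = seed)
    ip_pipeline(tht_timecourse(sim$mixture), tht_timecourse(sim$fragment),
                tht_timecourse(sim$parent), correction = sim$correction)$ip
  }
  expect_lt(abs(run_ip(mixture_truth(0), 31)), 10)
  expect_lt(abs(run_ip(mixture_truth(1), 32) - 100), 10)
})

test_that("amide trajectory crossover flips the dominant-class label", {
  traj <- tibble::tibble(
    time_h = c(0, 2, 4, 6, 8),
    beta_sheet = c(0.1, 0.3, 0.45, 0.6, 0.7),
    unordered = c(0.7, 0.5, 0.35, 0.2, 0.1),
    helix = 0.05,
    turn = c(0.15, 0.15, 0.15, 0.15, 0.15)
  )
  sp <- simulate_amide_series(traj, noise_sd = 0)
  labels <- purrr::map_chr(split_spectra_for_test(sp), function(one) {
    classify_ftir(decompose_amide_i(one))$label
  })
  expect_equal(unname(labels[1]), "unordered")
  expect_equal(unname(labels[5]), "beta_sheet")
  # the flip happens exactly when beta overtakes unordered (between 2 and 4 h)
  expect_equal(unname(labels), c("unordered", "unordered", "beta_sheet",
                                 "beta_sheet", "beta_sheet"))
})

test_that("emission pair with zero efficiency is perfectly additive", {
  obs <- observation_model(noise_sd = list(tht = 0, scattering = 0,
                                           emission = 0, ftir = 0),
                           replicate_cv = 0)
  pair <- simulate_emission_pair(truth = mixture_truth(), obs = obs,
                                 times = c(1, 10), replicates = 1)
  d <- ret_difference(pair$f_a, pair$f_b, pair$f_mix, time_h = 10,
                      sg_points = 0)
  expect_lt(max(abs(d$intensity)), 1e-10)
})
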