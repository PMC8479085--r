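#' Kinetic parameters for the two-step aggregation model
#'
#' Parameters of the Finke–Watzky two-step model (slow continuous nucleation
#' A \eqn{\to} B, autocatalytic growth A + B \eqn{\to} 2B) used as synthetic
#' ground-truth kinetics. The defaults describe a parent-peptide assay at 35
#' \eqn{\mu}M that saturates within about a day, matching lag-free
#' saturating ThT kinetics.
#'
#' @param k_n Pseudo-first-order nucleation rate, h\eqn{^{-1}}.
#' @param k_e Autocatalytic growth rate, \eqn{\mu}M\eqn{^{-1}}h\eqn{^{-1}}.
#' @param a0 Total peptide concentration, \eqn{\mu}M.
#' @param fibril_fraction_max Fraction of aggregated mass that is fibrillar
#'   (ThT-visible); the remainder is amorphous aggregate seen only by light
#'   scattering.
#' @return A list of class `"kinetic_params"`.
#' @export
kinetic_params <- function(k_n = 0.01, k_e = 0.01, a0 = 35,
                           fibril_fraction_max = 0.9) {
  stopifnot(k_n >= 0, k_e >= 0, a0 > 0,
            fibril_fraction_max >= 0, fibril_fraction_max <= 1)
  structure(list(k_n = k_n, k_e = k_e, a0 = a0,
                 fibril_fraction_max = fibril_fraction_max),
            class = "kinetic_params")
}

#' Finke–Watzky closed-form aggregate mass
#'
#' Closed form of the two-step nucleation/autocatalytic-growth model:
#' \deqn{W(t) = A_0 - \frac{k_n/k_e + A_0}{1 + (k_n/(k_e A_0))
#'   e^{(k_n + k_e A_0) t}}.}
#' `W(0) = 0` and `W(t) -> A0` as `t -> Inf`.
#'
#' @param times Non-negative, increasing time grid (hours).
#' @param k_n,k_e,a0 See [kinetic_params()].
#' @return Aggregated mass in \eqn{\mu}M at each time.
#' @export
finke_watzky <- function(times, k_n, k_e, a0) {
  stopifnot(all(times >= 0), !is.unsorted(times))
  if (k_e <= 0) {
    # pure first-order limit
    return(a0 * (1 - exp(-k_n * times)))
  }
  ratio <- k_n / (k_e * a0)
  a0 - (k_n / k_e + a0) / (1 + ratio * exp((k_n + k_e * a0) * times))
}

#' Deterministic aggregation curves
#'
#' Evaluates the Finke–Watzky model and splits aggregated mass into
#' fibrillar (ThT-visible) and amorphous components. Mass balance holds
#' exactly: `monomer + fibril + amorphous = a0` at every time.
#'
#' @param times Time grid in hours.
#' @param params A [kinetic_params()] object.
#' @return A tibble: `time_h`, `aggregate_uM`, `fibril_uM`, `amorphous_uM`,
#'   `monomer_uM`.
#' @export
#' @examples
#' simulate_aggregation(c(0, 12, 24, 48), kinetic_params())
simulate_aggregation <- function(times, params = kinetic_params()) {
  stopifnot(inherits(params, "kinetic_params"))
  w <- finke_watzky(times, params$k_n, params$k_e, params$a0)
  tibble::tibble(
    time_h = times,
    aggregate_uM = w,
    fibril_uM = params$fibril_fraction_max * w,
    amorphous_uM = (1 - params$fibril_fraction_max) * w,
    monomer_uM = params$a0 - w
  )
}

#' Observation model for synthetic spectra
#'
#' Maps ground-truth concentrations to noisy spectra. Emission bands are
#' Gaussian profiles normalised to 1 at their peak; noise is additive
#' Gaussian per point, optionally with a signal-proportional component, and
#' each replicate draws an overall amplitude factor (between-experiment
#' variability).
#'
#' @param tht_binding_capacity ThT fluorescence (a.u.) per \eqn{\mu}M fibril.
#' @param scattering_coefficient Scattered intensity (a.u.) per \eqn{\mu}M
#'   aggregate (fibrillar plus amorphous).
#' @param tht_centre,tht_fwhm ThT emission band (nm).
#' @param scatter_centre,scatter_fwhm Scattering band shape (nm).
#' @param phe_centre,phe_fwhm,tyr_centre,tyr_fwhm Intrinsic Phe and Tyr
#'   emission bands (nm); Phe and Tyr emit near 287 and 310 nm.
#' @param acceptor_yield Fraction of transferred quanta re-emitted by Tyr.
#' @param quench_drift_amplitude,quench_drift_tau Multiplicative Tyr
#'   quenching drift `1 - a * (1 - exp(-t/tau))` (water-exposure quenching
#'   developing over `tau` hours).
#' @param noise_sd Additive noise SD per modality, a named list with
#'   elements `tht`, `scattering`, `emission`, `ftir` (a.u.).
#' @param noise_cv Optional signal-proportional noise component (SD =
#'   `noise_cv * |signal|` added in quadrature); 0 = homoscedastic.
#' @param replicate_cv SD of the per-replicate amplitude factor.
#' @return A list of class `"observation_model"`.
#' @export
observation_model <- function(tht_binding_capacity = 2,
                              scattering_coefficient = 1.5,
                              tht_centre = 480, tht_fwhm = 30,
                              scatter_centre = 550, scatter_fwhm = 40,
                              phe_centre = 287, phe_fwhm = 24,
                              tyr_centre = 310, tyr_fwhm = 28,
                              acceptor_yield = 0.8,
                              quench_drift_amplitude = 0.15,
                              quench_drift_tau = 10,
                              noise_sd = list(tht = 2, scattering = 2,
                                              emission = 1, ftir = 0.004),
                              noise_cv = 0,
                              replicate_cv = 0.05) {
  stopifnot(tht_binding_capacity >= 0, scattering_coefficient >= 0,
            acceptor_yield >= 0, all(unlist(noise_sd) >= 0),
            noise_cv >= 0, replicate_cv >= 0)
  structure(
    list(
      tht_binding_capacity = tht_binding_capacity,
      scattering_coefficient = scattering_coefficient,
      tht_centre = tht_centre, tht_fwhm = tht_fwhm,
      scatter_centre = scatter_centre, scatter_fwhm = scatter_fwhm,
      phe_centre = phe_centre, phe_fwhm = phe_fwhm,
      tyr_centre = tyr_centre, tyr_fwhm = tyr_fwhm,
      acceptor_yield = acceptor_yield,
      quench_drift_amplitude = quench_drift_amplitude,
      quench_drift_tau = quench_drift_tau,
      noise_sd = noise_sd, noise_cv = noise_cv,
      replicate_cv = replicate_cv
    ),
    class = "observation_model"
  )
}

# Gaussian band profile, unit height at the centre.
band_profile <- function(axis, centre, fwhm) {
  exp(-0.5 * ((axis - centre) / (fwhm * FWHM_TO_SD))^2)
}

# Deterministic replicate-stream seed below 2^31.
derive_seed <- function(seed, replicate, stream = 0L) {
  as.integer((as.numeric(seed) * 97L + replicate * 1009L + stream * 10007L) %%
               2147483647)
}

add_noise <- function(mu, sd_base, noise_cv) {
  sd_i <- sqrt(sd_base^2 + (noise_cv * abs(mu))^2)
  mu + rnorm(length(mu), 0, sd_i)
}

# One noisy spectral series from a deterministic amplitude curve and a band
# shape. amplitudes: tibble(time_h, amp).
series_from_amplitudes <- function(amplitudes, axis, centre, fwhm, sd_base,
                                   obs, replicates, seed, stream,
                                   sample_id, modality) {
  profile <- band_profile(axis, centre, fwhm)
  purrr::map_dfr(seq_len(replicates), function(r) {
    set.seed(derive_seed(seed, r, stream))
    rep_factor <- 1 + rnorm(1, 0, obs$replicate_cv)
    purrr::map_dfr(seq_len(nrow(amplitudes)), function(i) {
      mu <- rep_factor * amplitudes$amp[i] * profile
      tibble::tibble(
        sample_id = sample_id, modality = modality,
        axis_kind = "wavelength_nm", replicate = r,
        time_h = amplitudes$time_h[i], axis = axis,
        intensity = add_noise(mu, sd_base, obs$noise_cv)
      )
    })
  }) %>% as_spectra()
}

#' Simulate a ThT emission spectral series
#'
#' Emission spectra (excitation 435 nm) whose band amplitude tracks the
#' fibril concentration: amplitude = `tht_binding_capacity * fibril_uM`,
#' band centred at 480 nm so the 475–485 nm window reads the fibril signal.
#'
#' @param curve Output of [simulate_aggregation()] (needs `time_h`,
#'   `fibril_uM`).
#' @param obs An [observation_model()].
#' @param replicates Number of replicates.
#' @param seed Master seed; replicate streams are derived deterministically.
#' @param axis Wavelength grid (nm).
#' @param sample_id Sample label.
#' @return A spectra tibble.
#' @export
simulate_tht_series <- function(curve, obs = observation_model(),
                                replicates = 3, seed = 1,
                                axis = seq(450, 520, by = 1),
                                sample_id = "sample") {
  stopifnot(is.data.frame(curve), all(c("time_h", "fibril_uM") %in% names(curve)))
  amps <- tibble::tibble(time_h = curve$time_h,
                         amp = obs$tht_binding_capacity * curve$fibril_uM)
  series_from_amplitudes(amps, axis, obs$tht_centre, obs$tht_fwhm,
                         obs$noise_sd$tht, obs, replicates, seed,
                         stream = 1L, sample_id = sample_id,
                         modality = "tht_fluorescence")
}

#' Simulate a light-scattering spectral series
#'
#' Scattered intensity around 550 nm proportional to total aggregate mass
#' (fibrillar plus amorphous), read by the 550–555 nm window.
#'
#' @inheritParams simulate_tht_series
#' @export
simulate_scattering_series <- function(curve, obs = observation_model(),
                                       replicates = 3, seed = 1,
                                       axis = seq(530, 570, by = 1),
                                       sample_id = "sample") {
  stopifnot(is.data.frame(curve),
            all(c("time_h", "aggregate_uM") %in% names(curve)))
  amps <- tibble::tibble(time_h = curve$time_h,
                         amp = obs$scattering_coefficient * curve$aggregate_uM)
  series_from_amplitudes(amps, axis, obs$scatter_centre, obs$scatter_fwhm,
                         obs$noise_sd$scattering, obs, replicates, seed,
                         stream = 2L, sample_id = sample_id,
                         modality = "scattering")
}

#' Ground truth for a mixture / interaction simulation
#'
#' @param true_inhibition Fractional suppression of parent fibril mass in
#'   the mixture, in \[0, 1\].
#' @param efficiency Transfer-efficiency profile for RET pairs: a function
#'   of time (hours) returning E in \[0, 1\].
#' @return A list of class `"mixture_truth"`.
#' @export
mixture_truth <- function(true_inhibition = 0, efficiency = function(t) 0 * t) {
  stopifnot(true_inhibition >= 0, true_inhibition <= 1,
            is.function(efficiency))
  structure(list(true_inhibition = true_inhibition, efficiency = efficiency),
            class = "mixture_truth")
}

#' Gaussian-in-time interaction profile
#'
#' Transient transfer-efficiency profile `E(t) = e_max *
#' exp(-((t - t_peak)/width)^2)`, emulating hetero-aggregates that form and
#' later fall apart as partners self-sort.
#'
#' @param e_max Peak efficiency.
#' @param t_peak Time of peak interaction, hours.
#' @param width Gaussian width, hours.
#' @return A function of time.
#' @export
interaction_profile <- function(e_max = 0.4, t_peak = 20, width = 8) {
  force(e_max); force(t_peak); force(width)
  function(t) e_max * exp(-((t - t_peak) / width)^2)
}

#' Simulate the inhibition-assay design
#'
#' Generates the three ThT series of the inhibition experiment: parent
#' peptide alone (35 \eqn{\mu}M by default), fragment alone at its reference
#' concentration (100 \eqn{\mu}M) and the mixture (parent at its alone
#' concentration plus fragment at `conc_frag_mix` = 70 \eqn{\mu}M). In the
#' mixture the parent fibril signal is suppressed by `truth$true_inhibition`
#' and the fragment contributes its own signal scaled by the concentration
#' ratio, assuming fluorescence linear in concentration. Running the three
#' series through [ip_pipeline()] with `correction = conc_frag_mix /
#' conc_frag_alone` recovers `100 * true_inhibition` up to noise.
#'
#' @param parent,frag [kinetic_params()] for the two peptides; `frag$a0` is
#'   the fragment-alone reference concentration.
#' @param truth A [mixture_truth()].
#' @param obs_parent,obs_frag [observation_model()]s; ThT binding capacity
#'   is per-peptide. The fragment default (0.5 vs 2 a.u. per \eqn{\mu}M)
#'   encodes that short-fragment aggregates bind far less ThT than parent
#'   fibrils, so fragment-alone plateau signals stay below the parent's.
#' @param times Time grid, hours.
#' @param replicates Replicates per series.
#' @param seed Master seed.
#' @param conc_frag_mix Fragment concentration in the mixture, \eqn{\mu}M.
#' @param axis Wavelength grid, nm.
#' @return A list with spectra tibbles `parent`, `fragment`, `mixture`, the
#'   `truth` object and the implied `correction` factor.
#' @export
simulate_mixture <- function(parent = kinetic_params(a0 = 35),
                             frag = kinetic_params(k_n = 0.005, k_e = 0.004,
                                                   a0 = 100),
                             truth = mixture_truth(),
                             obs_parent = observation_model(),
                             obs_frag = observation_model(
                               tht_binding_capacity = 0.5),
                             times = c(0, 2, 4, 8, 16, 24, 32, 40, 48),
                             replicates = 3, seed = 1,
                             conc_frag_mix = 70,
                             axis = seq(450, 520, by = 1)) {
  stopifnot(inherits(truth, "mixture_truth"))
  parent_curve <- simulate_aggregation(times, parent)
  frag_curve <- simulate_aggregation(times, frag)
  ratio <- conc_frag_mix / frag$a0

  parent_amp <- obs_parent$tht_binding_capacity * parent_curve$fibril_uM
  frag_amp <- obs_frag$tht_binding_capacity * frag_curve$fibril_uM
  mix_amp <- (1 - truth$true_inhibition) * parent_amp + ratio * frag_amp

  mk <- function(amp, obs, stream, sample_id) {
    series_from_amplitudes(
      tibble::tibble(time_h = times, amp = amp),
      axis, obs$tht_centre, obs$tht_fwhm, obs$noise_sd$tht,
      obs, replicates, seed, stream, sample_id, "tht_fluorescence"
    )
  }
  list(
    parent = mk(parent_amp, obs_parent, 11L, "parent"),
    fragment = mk(frag_amp, obs_frag, 12L, "fragment"),
    mixture = mk(mix_amp, obs_parent, 13L, "mixture"),
    truth = truth,
    correction = ratio
  )
}

#' Simulate an intrinsic-fluorescence RET pair
#'
#' Emission spectra (excitation 220 nm) for two peptides alone at full assay
#' concentration and their equimolar half-and-half mixture. In the mixture,
#' donor (Phe) emission is scaled by `1 - E(t)` and acceptor (Tyr) emission
#' gains the transferred quanta times `acceptor_yield`; the individual
#' spectra are non-interacting. A multiplicative quenching drift acts on all
#' Tyr emission (identically in individuals and mixture, so it cancels in
#' the difference procedure).
#'
#' @param truth A [mixture_truth()]; `truth$efficiency` drives the transfer.
#' @param obs An [observation_model()].
#' @param a_phe,a_tyr,b_phe,b_tyr Band amplitudes (a.u.) of peptides A and B
#'   alone at full concentration.
#' @param times Time grid, hours.
#' @param replicates,seed As elsewhere.
#' @param axis Wavelength grid, nm.
#' @return A list with spectra tibbles `f_a`, `f_b`, `f_mix` and `truth`.
#' @export
simulate_emission_pair <- function(truth = mixture_truth(
                                     efficiency = interaction_profile()),
                                   obs = observation_model(),
                                   a_phe = 100, a_tyr = 0,
                                   b_phe = 20, b_tyr = 80,
                                   times = c(0.5, 1, 2, 4, 8, 12, 16, 20, 24,
                                             30, 40, 50, 70, 100),
                                   replicates = 3, seed = 1,
                                   axis = seq(250, 350, by = 1)) {
  stopifnot(inherits(truth, "mixture_truth"))
  g_phe <- band_profile(axis, obs$phe_centre, obs$phe_fwhm)
  g_tyr <- band_profile(axis, obs$tyr_centre, obs$tyr_fwhm)
  drift <- function(t) {
    1 - obs$quench_drift_amplitude * (1 - exp(-t / obs$quench_drift_tau))
  }
  e_t <- truth$efficiency(times)
  stopifnot(all(e_t >= 0 & e_t <= 1))

  mk <- function(phe_amp, tyr_amp, stream, sample_id) {
    purrr::map_dfr(seq_len(replicates), function(r) {
      set.seed(derive_seed(seed, r, stream))
      rep_factor <- 1 + rnorm(1, 0, obs$replicate_cv)
      purrr::map_dfr(seq_along(times), function(i) {
        mu <- rep_factor * (phe_amp[i] * g_phe + tyr_amp[i] * g_tyr)
        tibble::tibble(
          sample_id = sample_id, modality = "emission",
          axis_kind = "wavelength_nm", replicate = r,
          time_h = times[i], axis = axis,
          intensity = add_noise(mu, obs$noise_sd$emission, obs$noise_cv)
        )
      })
    }) %>% as_spectra()
  }

  ones <- rep(1, length(times))
  dr <- drift(times)
  list(
    f_a = mk(a_phe * ones, a_tyr * dr, 21L, "A"),
    f_b = mk(b_phe * ones, b_tyr * dr, 22L, "B"),
    f_mix = mk(
      0.5 * (a_phe + b_phe) * (1 - e_t),
      0.5 * (a_tyr + b_tyr) * dr +
        0.5 * (a_phe + b_phe) * e_t * obs$acceptor_yield,
      23L, "A+B"
    ),
    truth = truth
  )
}

#' Simulate an amide-I FTIR spectral series
#'
#' Each spectrum is the area-weighted sum of the band Gaussians (unit total
#' area times `total_area`) for the supplied fraction trajectory, plus
#' additive noise.
#'
#' @param trajectories A tibble with column `time_h` and one column per band
#'   label in `bands` giving its area fraction at that time (rows must sum
#'   to 1).
#' @param bands Band definitions, see [amide_bands()].
#' @param total_area Total amide-I band area (absorbance *
#'   cm\eqn{^{-1}}).
#' @param noise_sd Additive noise SD (absorbance units).
#' @param replicates,seed As elsewhere.
#' @param axis Wavenumber grid, cm\eqn{^{-1}}.
#' @return A spectra tibble with `axis_kind = "wavenumber_cm1"`.
#' @export
simulate_amide_series <- function(trajectories, bands = amide_bands(),
                                  total_area = 10, noise_sd = 0.004,
                                  replicates = 1, seed = 1,
                                  axis = seq(1580, 1720, by = 2)) {
  stopifnot(is.data.frame(trajectories), "time_h" %in% names(trajectories))
  bands <- validate_bands(bands)
  fr <- as.matrix(trajectories[, bands$label, drop = FALSE])
  if (any(abs(rowSums(fr) - 1) > 1e-6)) {
    abort("Fraction trajectories must sum to 1 at every time point.")
  }
  sd_b <- bands$fwhm * FWHM_TO_SD
  # unit-area component shapes
  shapes <- vapply(seq_len(nrow(bands)), function(k) {
    exp(-0.5 * ((axis - bands$centre[k]) / sd_b[k])^2) / (sd_b[k] * sqrt(2 * pi))
  }, numeric(length(axis)))
  purrr::map_dfr(seq_len(replicates), function(r) {
    set.seed(derive_seed(seed, r, 31L))
    purrr::map_dfr(seq_len(nrow(trajectories)), function(i) {
      mu <- as.numeric(shapes %*% (total_area * fr[i, ]))
      tibble::tibble(
        sample_id = "amide", modality = "ftir",
        axis_kind = "wavenumber_cm1", replicate = r,
        time_h = trajectories$time_h[i], axis = axis,
        intensity = mu + rnorm(length(mu), 0, noise_sd)
      )
    })
  }) %>% as_spectra()
}
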