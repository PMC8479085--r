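nearest_time <- function(spectra, time_h, tol) {
  times <- unique(spectra$time_h)
  d <- abs(times - time_h)
  if (min(d) > tol) {
    abort(sprintf(
      "No spectrum of '%s' within %g h of t = %g h (nearest: %g h).",
      spectra$sample_id[[1]], tol, time_h, times[which.min(d)]
    ))
  }
  dplyr::filter(spectra, .data$time_h == times[which.min(d)])
}

#' RET difference spectrum
#'
#' The Phe\eqn{\to}Tyr resonance-energy-transfer screen compares an
#' equimolar peptide mixture (each partner at half its individual assay
#' concentration, keeping total peptide constant) with the two individual
#' spectra: each input is Savitzky–Golay smoothed, then
#' \deqn{D = s \cdot F_{mix} - F_A - F_B,} with `scale` (s) defaulting to 2
#' for the half-and-half mixing design. For a non-interacting pair the
#' mixture is additive and `D` vanishes identically; donor quenching
#' (negative `D` over the Phe window) with acceptor enhancement (positive
#' over the Tyr window) indicates energy transfer.
#'
#' @param f_a,f_b,f_mix Emission spectra tibbles for peptide A alone,
#'   peptide B alone and the mixture (shared wavelength grid).
#' @param time_h Incubation time to analyse; each series contributes its
#'   nearest spectrum within `time_tol`.
#' @param replicate Replicate index to use.
#' @param scale Mixture multiplier, default 2.
#' @param sg_points,sg_order Savitzky–Golay settings applied to every input
#'   before subtraction (13-point quadratic by default); `sg_points = 0`
#'   disables smoothing.
#' @param time_tol Nearest-neighbour time-matching tolerance in hours.
#' @return A single-acquisition spectra tibble holding the difference
#'   spectrum, tagged with the matched time.
#' @export
ret_difference <- function(f_a, f_b, f_mix, time_h, replicate = 1L,
                           scale = 2, sg_points = 13, sg_order = 2,
                           time_tol = 0.5) {
  stopifnot(scale > 0)
  pick <- function(s) {
    stopifnot(is.data.frame(s))
    # subset first, validate the single acquisition (cheap on hot paths)
    s <- s[s$replicate == replicate, , drop = FALSE]
    if (!nrow(s)) abort("Requested replicate not present in a series.")
    s <- as_spectra(nearest_time(s, time_h, time_tol))
    if (sg_points > 0) s <- savitzky_golay(s, sg_points, sg_order)
    s
  }
  a <- pick(f_a); b <- pick(f_b); m <- pick(f_mix)
  d <- combine_spectra(m, a, ca = scale, cb = -1)
  d <- combine_spectra(d, b, ca = 1, cb = -1,
                       sample_id = sprintf("RET[%s|%s]", a$sample_id[[1]],
                                           b$sample_id[[1]]))
  d$time_h <- m$time_h[[1]]
  d$replicate <- as.integer(replicate)
  d
}

#' Windowed RET difference metrics
#'
#' Band averages of a difference spectrum over the donor and acceptor
#' emission windows: 270–290 nm for phenylalanine and 300–320 nm for
#' tyrosine.
#'
#' @param d A difference spectrum from [ret_difference()].
#' @param phe_window,tyr_window Averaging windows in nm.
#' @return One-row tibble: `sample_id`, `replicate`, `time_h`, `dF_phe`,
#'   `dF_tyr`.
#' @export
ret_metrics <- function(d, phe_window = c(270, 290), tyr_window = c(300, 320)) {
  d <- as_spectra(d)
  tibble::tibble(
    sample_id = d$sample_id[[1]],
    replicate = d$replicate[[1]],
    time_h = d$time_h[[1]],
    dF_phe = band_average(d, phe_window[1], phe_window[2])$value,
    dF_tyr = band_average(d, tyr_window[1], tyr_window[2])$value
  )
}

#' Sign-based RET call
#'
#' Energy transfer is called when donor fluorescence is reduced and acceptor
#' fluorescence enhanced beyond a noise floor:
#' `dF_phe < -noise_floor` and `dF_tyr > +noise_floor`. The margin
#' `min(|dF_phe|, dF_tyr) - noise_floor` quantifies how far the weaker of
#' the two signs clears the floor. The default floor of 0 reproduces a bare
#' sign test; see [ret_noise_floor()] for a floor estimated from baseline
#' spread.
#'
#' @param metrics A tibble with columns `dF_phe` and `dF_tyr`
#'   (see [ret_metrics()]); any number of rows.
#' @param noise_floor Non-negative threshold in intensity units.
#' @return `metrics` with logical `ret` and numeric `margin` appended.
#' @export
#' @examples
#' detect_ret(tibble::tibble(dF_phe = -5, dF_tyr = 3))
detect_ret <- function(metrics, noise_floor = 0) {
  stopifnot(is.data.frame(metrics),
            all(c("dF_phe", "dF_tyr") %in% names(metrics)))
  if (noise_floor < 0) abort("`noise_floor` must be non-negative.")
  dplyr::mutate(
    tibble::as_tibble(metrics),
    ret = .data$dF_phe < -noise_floor & .data$dF_tyr > noise_floor,
    margin = pmin(abs(.data$dF_phe), .data$dF_tyr) - noise_floor
  )
}

#' Noise floor from baseline RET metrics
#'
#' Robust alternative to the bare sign test: the floor is `k` times the SD
#' of the pooled donor/acceptor difference metrics collected during a
#' baseline period (before any interaction has developed, e.g. the first
#' hours after mixing), when the expected difference signal is zero.
#'
#' @param metrics A metrics tibble (rows over times/replicates).
#' @param baseline_t_max Times `<= baseline_t_max` hours form the baseline.
#' @param k Multiplier on the baseline SD, default 3.
#' @return A non-negative scalar noise floor.
#' @export
ret_noise_floor <- function(metrics, baseline_t_max, k = 3) {
  stopifnot(is.data.frame(metrics), "time_h" %in% names(metrics))
  base <- dplyr::filter(metrics, .data$time_h <= baseline_t_max)
  if (nrow(base) < 2) abort("Need at least 2 baseline metric rows.")
  k * sd(c(base$dF_phe, base$dF_tyr))
}

#' Förster transfer efficiency
#'
#' Efficiency of resonance energy transfer between a donor/acceptor pair at
#' separation `r`: \deqn{E = R_0^6 / (R_0^6 + r^6),} so `E = 0.5` exactly at
#' the Förster distance. The Phe\eqn{\to}Tyr pair has an unusually short
#' `R0` of 13.5 Å.
#'
#' @param r Donor–acceptor distance(s), Å, \eqn{\ge} 0.
#' @param r0 Förster distance, Å, default 13.5.
#' @return Efficiency in \[0, 1\], same length as `r`.
#' @export
#' @examples
#' forster_efficiency(13.5) # 0.5
forster_efficiency <- function(r, r0 = 13.5) {
  stopifnot(is.numeric(r), is.numeric(r0), length(r0) == 1)
  if (r0 <= 0) abort("`r0` must be positive.")
  if (any(r < 0)) abort("`r` must be non-negative.")
  r0^6 / (r0^6 + r^6)
}
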