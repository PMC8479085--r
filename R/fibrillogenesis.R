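timecourse_from_band <- function(spectra, lo, hi, modality_label) {
  tc <- band_average(spectra, lo, hi) %>%
    dplyr::transmute(
      modality = modality_label,
      sample_id = .data$sample_id,
      replicate = .data$replicate,
      time_h = .data$time_h,
      value = .data$value
    ) %>%
    dplyr::arrange(.data$sample_id, .data$replicate, .data$time_h)
  attr(tc, "window") <- c(lo, hi)
  tc
}

#' Thioflavin-T fluorescence time course
#'
#' Reduces a series of ThT emission spectra (excitation 435 nm) to an
#' aggregation time course: per spectrum, mean fluorescence over 475–485 nm,
#' grouped by replicate and plotted against incubation time.
#'
#' @param spectra An emission spectra tibble covering 475–485 nm.
#' @param window Averaging window in nm, default `c(475, 485)`.
#' @return A time-course tibble: `modality`, `sample_id`, `replicate`,
#'   `time_h`, `value`, with the window stored as an attribute.
#' @export
tht_timecourse <- function(spectra, window = c(475, 485)) {
  spectra <- as_spectra(spectra)
  if (any(spectra$axis_kind != "wavelength_nm")) {
    abort("ThT time course needs emission spectra on a wavelength axis.")
  }
  timecourse_from_band(spectra, window[1], window[2], "tht_fluorescence")
}

#' 90-degree light-scattering time course
#'
#' Mean scattered intensity over 550–555 nm (incident light 550 nm) per
#' spectrum, grouped by replicate — the aggregate-mass readout that, unlike
#' ThT, also reports non-fibrillar aggregates.
#'
#' @param spectra A scattering spectra tibble covering 550–555 nm.
#' @param window Averaging window in nm, default `c(550, 555)`.
#' @inherit tht_timecourse return
#' @export
scattering_timecourse <- function(spectra, window = c(550, 555)) {
  spectra <- as_spectra(spectra)
  if (any(spectra$axis_kind != "wavelength_nm")) {
    abort("Scattering time course needs spectra on a wavelength axis.")
  }
  timecourse_from_band(spectra, window[1], window[2], "scattering")
}

validate_timecourse <- function(tc, arg = "tc") {
  stopifnot(is.data.frame(tc))
  needed <- c("replicate", "time_h", "value")
  missing <- setdiff(needed, names(tc))
  if (length(missing)) {
    abort(sprintf("`%s` is missing time-course column(s): %s.",
                  arg, paste(missing, collapse = ", ")))
  }
  if (any(tc$time_h < 0)) abort(sprintf("`%s` has negative times.", arg))
  tibble::as_tibble(tc)
}

#' Plateau summary of a time course over a time window
#'
#' Per-replicate mean of the values falling in the closed window
#' `[t_lo, t_hi]` hours, plus the grand mean and across-replicate sample SD —
#' the plateau reduction used for the inhibition statistic (32–48 h by
#' default there). With a single replicate the SD is reported as 0 and the
#' result is flagged `small_n`.
#'
#' @param tc A time-course tibble (see [tht_timecourse()]).
#' @param t_lo,t_hi Window bounds in hours.
#' @return A list of class `"window_mean"`: `per_replicate` (tibble
#'   `replicate`, `mean`, `n_points`), `mean`, `sd`, `n`, `small_n`,
#'   `window`.
#' @export
#' @examples
#' tc <- tibble::tibble(replicate = rep(1:3, each = 2),
#'                      time_h = rep(c(35, 45), 3),
#'                      value = rep(c(10, 20, 30), each = 2))
#' window_mean(tc, 32, 48)
window_mean <- function(tc, t_lo, t_hi) {
  tc <- validate_timecourse(tc)
  stopifnot(t_lo < t_hi)
  per <- tc %>%
    dplyr::group_by(.data$replicate) %>%
    dplyr::summarise(
      mean = mean(.data$value[.data$time_h >= t_lo & .data$time_h <= t_hi]),
      n_points = sum(.data$time_h >= t_lo & .data$time_h <= t_hi),
      .groups = "drop"
    )
  if (any(per$n_points == 0)) {
    abort(sprintf(
      "Replicate(s) %s have no time points in [%g, %g] h.",
      paste(per$replicate[per$n_points == 0], collapse = ", "), t_lo, t_hi
    ))
  }
  n <- nrow(per)
  structure(
    list(
      per_replicate = per,
      mean = mean(per$mean),
      sd = if (n > 1) sd(per$mean) else 0,
      n = n,
      small_n = n < 2,
      window = c(t_lo, t_hi)
    ),
    class = "window_mean"
  )
}

#' @export
print.window_mean <- function(x, ...) {
  cat(sprintf("Window mean over [%g, %g] h: %.4g +/- %.4g (n = %d%s)\n",
              x$window[1], x$window[2], x$mean, x$sd, x$n,
              if (x$small_n) ", small-n: SD reported as 0" else ""))
  invisible(x)
}
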