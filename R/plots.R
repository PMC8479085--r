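#' Plot spectra coloured by incubation time
#'
#' @param spectra A spectra tibble.
#' @param replicate Replicate to show (default: first present).
#' @return A ggplot object.
#' @export
plot_spectra <- function(spectra, replicate = NULL) {
  spectra <- as_spectra(spectra)
  if (is.null(replicate)) replicate <- min(spectra$replicate)
  df <- dplyr::filter(spectra, .data$replicate == .env$replicate)
  xlab <- if (df$axis_kind[[1]] == "wavenumber_cm1") {
    expression(Wavenumber ~ (cm^-1))
  } else {
    "Wavelength (nm)"
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$axis, .data$intensity,
                                   colour = factor(.data$time_h),
                                   group = .data$time_h)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$sample_id), scales = "free_y") +
    ggplot2::labs(x = xlab, y = "Intensity (a.u.)", colour = "Time (h)") +
    ggplot2::theme_minimal()
}

#' Plot an aggregation time course
#'
#' Replicate traces with the replicate-mean overlaid; optionally shades the
#' plateau window used for summaries.
#'
#' @param tc A time-course tibble (see [tht_timecourse()]).
#' @param window Optional two-element window in hours to shade.
#' @return A ggplot object.
#' @export
plot_timecourse <- function(tc, window = NULL) {
  tc <- validate_timecourse(tc)
  p <- ggplot2::ggplot(tc, ggplot2::aes(.data$time_h, .data$value))
  if (!is.null(window)) {
    p <- p + ggplot2::annotate("rect", xmin = window[1], xmax = window[2],
                               ymin = -Inf, ymax = Inf, alpha = 0.15)
  }
  p +
    ggplot2::geom_line(ggplot2::aes(group = .data$replicate), alpha = 0.4) +
    ggplot2::stat_summary(fun = mean, geom = "line", linewidth = 1) +
    ggplot2::labs(x = "Incubation time (h)", y = "Signal (a.u.)") +
    ggplot2::theme_minimal()
}

#' Bar plot of inhibition percentages
#'
#' @param results A named list of `"inhibition_result"` objects (names are
#'   fragment labels) or a tibble with columns `name`, `ip`, `sd`.
#' @return A ggplot object.
#' @export
plot_inhibition <- function(results) {
  if (!is.data.frame(results)) {
    results <- purrr::imap_dfr(results, function(r, nm) {
      tibble::tibble(name = nm, ip = r$ip, sd = r$sd)
    })
  }
  ggplot2::ggplot(results, ggplot2::aes(.data$name, .data$ip)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ip - .data$sd,
                                        ymax = .data$ip + .data$sd),
                           width = 0.25) +
    ggplot2::labs(x = NULL, y = "Inhibition (%)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot an amide-I decomposition
#'
#' Stacked view of the fitted component bands.
#'
#' @param object An `"amide_fit"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot amide_fit
#' @export
autoplot.amide_fit <- function(object, ...) {
  fr <- object$fractions
  ggplot2::ggplot(fr, ggplot2::aes(.data$label, .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Fraction of amide-I area",
                  title = sprintf("%s, t = %g h", object$sample_id,
                                  object$time_h)) +
    ggplot2::theme_minimal()
}

#' Autoplot RET metrics over time
#'
#' @param object A metrics tibble accumulated over times (rows from
#'   [ret_metrics()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_ret_metrics <- function(object, ...) {
  df <- tidyr::pivot_longer(object, c("dF_phe", "dF_tyr"),
                            names_to = "channel", values_to = "dF")
  ggplot2::ggplot(df, ggplot2::aes(.data$time_h, .data$dF,
                                   colour = .data$channel)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(x = "Incubation time (h)", y = expression(Delta * F ~ (a.u.)),
                  colour = NULL) +
    ggplot2::theme_minimal()
}
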