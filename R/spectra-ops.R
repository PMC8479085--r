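#' Windowed band average
#'
#' Arithmetic mean of the intensities at axis points inside the closed
#' interval `[lo, hi]`, computed per acquisition. This is the reduction used
#' throughout the assay: thioflavin-T fluorescence averaged over 475–485 nm,
#' 90-degree light scattering over 550–555 nm, RET difference signals over
#' 270–290 nm (Phe) and 300–320 nm (Tyr).
#'
#' @param spectra A spectra tibble (any number of acquisitions).
#' @param lo,hi Window bounds in axis units, `lo < hi`; both ends inclusive.
#' @return A tibble with one row per acquisition: the key columns plus
#'   `value` (the windowed mean) and `n_points`.
#' @export
#' @examples
#' s <- spectrum(400:500, rep(3, 101))
#' band_average(s, 475, 485)$value
band_average <- function(spectra, lo, hi) {
  spectra <- as_spectra(spectra)
  stopifnot(is.numeric(lo), is.numeric(hi), length(lo) == 1, length(hi) == 1)
  if (lo >= hi) abort("`lo` must be smaller than `hi`.")
  out <- spectra %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(SPECTRUM_KEYS))) %>%
    dplyr::summarise(
      value = mean(.data$intensity[.data$axis >= lo & .data$axis <= hi]),
      n_points = sum(.data$axis >= lo & .data$axis <= hi),
      .groups = "drop"
    )
  if (any(out$n_points == 0)) {
    span <- range(spectra$axis)
    abort(sprintf(
      "Window [%g, %g] contains no axis points (axis spans [%g, %g]).",
      lo, hi, span[1], span[2]
    ))
  }
  out
}

# Central Savitzky-Golay convolution weights (points taps, polynomial order).
sg_weights <- function(points, order) {
  proj <- signal::sgolay(p = order, n = points)
  as.numeric(proj[(points + 1) / 2, ])
}

#' Savitzky–Golay smoothing
#'
#' Least-squares polynomial smoothing on a uniformly spaced axis. Each
#' interior point is replaced by the value of the local polynomial fit over a
#' `points`-wide window; the defaults (13 points, order 2) are the classical
#' smoothing settings used on the emission spectra before the RET
#' subtraction. Edges are handled by reflect-padding (`edge = "reflect"`,
#' default) or by the asymmetric least-squares fits of the projection matrix
#' (`edge = "fit"`).
#'
#' @param spectra A spectra tibble.
#' @param points Odd window width (taps).
#' @param order Polynomial order, `order < points`.
#' @param edge `"reflect"` or `"fit"`.
#' @param uniform_tol Relative tolerance on axis-spacing uniformity.
#' @return The spectra tibble with smoothed intensities; axis unchanged.
#' @export
savitzky_golay <- function(spectra, points = 13, order = 2,
                           edge = c("reflect", "fit"), uniform_tol = 1e-6) {
  edge <- match.arg(edge)
  spectra <- as_spectra(spectra)
  stopifnot(points %% 2 == 1, order < points, points >= 3)
  smooth_one <- function(df) {
    df <- dplyr::arrange(df, .data$axis)
    d <- diff(df$axis)
    span <- max(df$axis) - min(df$axis)
    if ((max(d) - min(d)) > uniform_tol * span) {
      abort("Axis is not uniformly spaced; resample before Savitzky-Golay smoothing.")
    }
    y <- df$intensity
    n <- length(y)
    if (n < points) {
      abort(sprintf("Spectrum has %d points; at least %d required.", n, points))
    }
    if (edge == "fit") {
      df$intensity <- as.numeric(signal::sgolayfilt(y, p = order, n = points))
    } else {
      h <- (points - 1) / 2
      padded <- c(y[(h + 1):2], y, y[(n - 1):(n - h)])
      w <- sg_weights(points, order)
      df$intensity <- as.numeric(stats::filter(padded, w, sides = 2))[(h + 1):(h + n)]
    }
    df
  }
  split_spectra(spectra) %>%
    purrr::map(smooth_one) %>%
    dplyr::bind_rows() %>%
    as_spectra()
}

#' Linear combination of two spectra
#'
#' Pointwise `ca * a + cb * b`. Axes must share the same kind; if the grids
#' differ by more than `align_tol` of the axis span, both spectra are
#' linearly interpolated onto the union of their axis points restricted to
#' the overlapping range. Metadata (sample, time, replicate) are taken from
#' `a` unless overridden.
#'
#' @param a,b Spectra tibbles each holding a single acquisition.
#' @param ca,cb Scalar coefficients.
#' @param sample_id Optional sample label for the result.
#' @param align_tol Relative axis-matching tolerance (fraction of span).
#' @return A single-acquisition spectra tibble on the common grid.
#' @export
combine_spectra <- function(a, b, ca = 1, cb = 1, sample_id = NULL,
                            align_tol = 1e-6) {
  a <- as_spectra(a); b <- as_spectra(b)
  if (length(split_spectra(a)) != 1L || length(split_spectra(b)) != 1L) {
    abort("`combine_spectra()` takes a single acquisition on each side.")
  }
  if (a$axis_kind[[1]] != b$axis_kind[[1]]) {
    abort("Cannot combine spectra with different axis kinds.")
  }
  a <- dplyr::arrange(a, .data$axis); b <- dplyr::arrange(b, .data$axis)
  span <- max(a$axis, b$axis) - min(a$axis, b$axis)
  same_grid <- nrow(a) == nrow(b) &&
    max(abs(a$axis - b$axis)) <= align_tol * span
  if (same_grid) {
    grid <- a$axis
    ya <- a$intensity
    yb <- b$intensity
  } else {
    lo <- max(min(a$axis), min(b$axis))
    hi <- min(max(a$axis), max(b$axis))
    if (lo >= hi) abort("Axes of the two spectra do not overlap.")
    grid <- sort(unique(c(a$axis, b$axis)))
    grid <- grid[grid >= lo & grid <= hi]
    ya <- approx(a$axis, a$intensity, xout = grid)$y
    yb <- approx(b$axis, b$intensity, xout = grid)$y
  }
  spectrum(
    axis = grid,
    intensity = ca * ya + cb * yb,
    axis_kind = a$axis_kind[[1]],
    sample_id = sample_id %||%
      paste0(ca, "*", a$sample_id[[1]], "+", cb, "*", b$sample_id[[1]]),
    modality = a$modality[[1]],
    time_h = a$time_h[[1]],
    replicate = a$replicate[[1]]
  )
}
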