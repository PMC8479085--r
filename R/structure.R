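#' Default amide-I band set
#'
#' Component bands used to decompose the amide-I region (1600–1700
#' cm\eqn{^{-1}}): intermolecular \eqn{\beta}-sheet near 1627
#' cm\eqn{^{-1}}, unordered/loop near 1647 cm\eqn{^{-1}}, \eqn{\alpha}-helix
#' near 1658 cm\eqn{^{-1}} and \eqn{\beta}-turn near 1672 cm\eqn{^{-1}}.
#' Widths are full widths at half maximum; each centre may float by
#' `centre_tol` during fitting, wide enough to span the paired positions
#' seen across peptides (1627/1623, 1647/1640, 1672/1670).
#'
#' @param centre_tol Allowed centre shift, cm\eqn{^{-1}}.
#' @param fwhm_min,fwhm_max Width bounds, cm\eqn{^{-1}}.
#' @return A tibble with columns `label`, `centre`, `fwhm`, `centre_tol`,
#'   `fwhm_min`, `fwhm_max`.
#' @export
amide_bands <- function(centre_tol = 4, fwhm_min = 8, fwhm_max = 40) {
  tibble::tibble(
    label = c("beta_sheet", "unordered", "helix", "turn"),
    centre = c(1627, 1647, 1658, 1672),
    fwhm = c(24, 28, 18, 22),
    centre_tol = centre_tol,
    fwhm_min = fwhm_min,
    fwhm_max = fwhm_max
  )
}

validate_bands <- function(bands) {
  stopifnot(is.data.frame(bands),
            all(c("label", "centre", "fwhm") %in% names(bands)))
  if (anyDuplicated(bands$centre)) abort("Band centres must be distinct.")
  if (any(bands$fwhm <= 0)) abort("Band widths must be positive.")
  if (any(bands$centre < 1600 | bands$centre > 1700)) {
    abort("Band centres must lie in the amide-I region [1600, 1700].")
  }
  if (!"centre_tol" %in% names(bands)) bands$centre_tol <- 4
  if (!"fwhm_min" %in% names(bands)) bands$fwhm_min <- 8
  if (!"fwhm_max" %in% names(bands)) bands$fwhm_max <- 40
  bands
}

FWHM_TO_SD <- 1 / (2 * sqrt(2 * log(2)))

gauss_mat <- function(axis, centre, sd) {
  vapply(seq_along(centre), function(k) {
    exp(-0.5 * ((axis - centre[k]) / sd[k])^2)
  }, numeric(length(axis)))
}

#' Decompose an amide-I spectrum into structure fractions
#'
#' Fits a sum of Gaussian component bands to the amide-I region by
#' constrained least squares: amplitudes are non-negative, centres may move
#' at most `centre_tol` from their nominal positions and widths stay within
#' the configured FWHM bounds. Reported fractions are component areas over
#' total fitted area, so they are invariant to uniform intensity scaling.
#' A poor fit (relative residual above `flag_threshold`) or an all-zero
#' input is flagged, not raised.
#'
#' @param spectra A single FTIR acquisition (axis kind `"wavenumber_cm1"`)
#'   covering \[1600, 1700\] cm\eqn{^{-1}}.
#' @param bands Band definition tibble, see [amide_bands()].
#' @param flag_threshold Relative RMS residual above which the fit is flagged.
#' @return An object of class `"amide_fit"`: a list with elements
#'   `fractions` (tibble `label`, `fraction`, `centre`, `fwhm`, `area`),
#'   `residual` (relative RMS residual), `flagged`, `flag_reason`, and the
#'   acquisition keys. Use [tidy()][generics::tidy] / [glance()] to extract
#'   tibbles, [classify_ftir()] for the dominant class.
#' @export
decompose_amide_i <- function(spectra, bands = amide_bands(),
                              flag_threshold = 0.1) {
  spectra <- as_spectra(spectra)
  if (length(split_spectra(spectra)) != 1L) {
    abort("`decompose_amide_i()` takes a single acquisition; map over groups.")
  }
  if (spectra$axis_kind[[1]] != "wavenumber_cm1") {
    abort("Amide-I decomposition needs a wavenumber axis.")
  }
  if (min(spectra$axis) > 1600 || max(spectra$axis) < 1700) {
    abort("Axis must cover the amide-I region [1600, 1700] cm^-1.")
  }
  bands <- validate_bands(bands)
  spectra <- dplyr::arrange(spectra, .data$axis)
  keep <- spectra$axis >= 1600 & spectra$axis <= 1700
  x <- spectra$axis[keep]
  y <- spectra$intensity[keep]
  nb <- nrow(bands)

  keys <- spectra[1, SPECTRUM_KEYS]
  result <- function(amp, centre, sd, residual, flagged, reason) {
    area <- amp * sd * sqrt(2 * pi)
    total <- sum(area)
    frac <- if (total > 0) area / total else rep(NA_real_, nb)
    structure(
      c(
        list(
          fractions = tibble::tibble(
            label = bands$label, fraction = frac,
            centre = centre, fwhm = sd / FWHM_TO_SD, area = area
          ),
          residual = residual, flagged = flagged, flag_reason = reason
        ),
        as.list(keys)
      ),
      class = "amide_fit"
    )
  }

  scale_y <- max(abs(y))
  if (scale_y == 0) {
    return(result(rep(0, nb), bands$centre, bands$fwhm * FWHM_TO_SD,
                  residual = 0, flagged = TRUE,
                  reason = "degenerate input: all-zero spectrum"))
  }

  sd0 <- bands$fwhm * FWHM_TO_SD
  # amplitude-only non-negative fit at nominal centres/widths as start
  amp0 <- as.numeric(pracma::lsqnonneg(gauss_mat(x, bands$centre, sd0), y)$x)

  par0 <- c(amp0, bands$centre, sd0)
  lower <- c(rep(0, nb), bands$centre - bands$centre_tol,
             bands$fwhm_min * FWHM_TO_SD)
  upper <- c(rep(Inf, nb), bands$centre + bands$centre_tol,
             bands$fwhm_max * FWHM_TO_SD)
  model <- function(par) {
    amp <- par[1:nb]; centre <- par[nb + 1:nb]; sd <- par[2 * nb + 1:nb]
    as.numeric(gauss_mat(x, centre, sd) %*% amp)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = par0,
      fn = function(par) y - model(par),
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    par <- par0
  } else {
    par <- fit$par
    # re-solve amplitudes exactly at the fitted shapes (guards nnls feasibility)
    par[1:nb] <- as.numeric(
      pracma::lsqnonneg(gauss_mat(x, par[nb + 1:nb], par[2 * nb + 1:nb]), y)$x
    )
  }
  resid <- y - model(par)
  rel_res <- sqrt(mean(resid^2)) / scale_y
  flagged <- rel_res > flag_threshold
  result(par[1:nb], par[nb + 1:nb], par[2 * nb + 1:nb],
         residual = rel_res, flagged = flagged,
         reason = if (flagged) sprintf("relative residual %.3g above threshold %.3g",
                                       rel_res, flag_threshold) else NA_character_)
}

#' @export
print.amide_fit <- function(x, ...) {
  cat(sprintf("Amide-I decomposition: %s, t = %g h (replicate %d)\n",
              x$sample_id, x$time_h, x$replicate))
  print(x$fractions)
  cat(sprintf("relative RMS residual: %.4g%s\n", x$residual,
              if (isTRUE(x$flagged)) sprintf("  [FLAGGED: %s]", x$flag_reason) else ""))
  invisible(x)
}

#' Dominant secondary-structure class from amide-I fractions
#'
#' Largest-fraction class; exact ties are broken by the fixed priority
#' beta_sheet > turn > helix > unordered. The margin to the runner-up is
#' reported alongside.
#'
#' @param fit An `"amide_fit"` object or a tibble with columns `label` and
#'   `fraction`.
#' @return A one-row tibble: `label`, `fraction`, `margin`.
#' @export
classify_ftir <- function(fit) {
  fractions <- if (inherits(fit, "amide_fit")) fit$fractions else fit
  stopifnot(is.data.frame(fractions),
            all(c("label", "fraction") %in% names(fractions)))
  if (anyNA(fractions$fraction)) {
    return(tibble::tibble(label = NA_character_, fraction = NA_real_,
                          margin = NA_real_))
  }
  priority <- c(beta_sheet = 1, turn = 2, helix = 3, unordered = 4)
  ord <- order(-fractions$fraction, priority[fractions$label])
  top <- fractions[ord[1], ]
  runner <- if (nrow(fractions) > 1) fractions$fraction[ord[2]] else 0
  tibble::tibble(label = top$label, fraction = top$fraction,
                 margin = top$fraction - runner)
}

# interior local minima: slope changes from negative to positive
local_minima <- function(y) {
  which(diff(sign(diff(y))) > 0) + 1L
}

#' Classify a far-UV CD spectrum by band position
#'
#' Rule-based secondary-structure call mirroring positional interpretation of
#' far-UV CD:
#' * `beta_sheet`: negative extremum in 215–225 nm together with positive
#'   ellipticity in 195–205 nm (the pattern of \eqn{\beta}-sheet formation);
#' * `helix`: two negative extrema near 208 nm and 220–225 nm without the
#'   positive 195–205 nm signal;
#' * `unordered`: dominant negative extremum at 195–203 nm;
#' * `mixed_turn`: anything else (including flat spectra).
#'
#' Thresholds are relative to the largest absolute ellipticity, so the call
#' is invariant to positive rescaling.
#'
#' @param spectra A single CD acquisition (wavelength axis covering at least
#'   195–240 nm).
#' @param rel_floor Fraction of `max(abs(intensity))` below which a signal is
#'   treated as zero.
#' @return A one-row tibble: keys plus `label`.
#' @export
classify_cd <- function(spectra, rel_floor = 0.05) {
  spectra <- as_spectra(spectra)
  if (length(split_spectra(spectra)) != 1L) {
    abort("`classify_cd()` takes a single acquisition; map over groups.")
  }
  if (spectra$axis_kind[[1]] != "wavelength_nm") {
    abort("CD classification needs a wavelength axis.")
  }
  if (min(spectra$axis) > 195 || max(spectra$axis) < 240) {
    abort("Axis must cover [195, 240] nm for CD classification.")
  }
  spectra <- dplyr::arrange(spectra, .data$axis)
  x <- spectra$axis
  y <- spectra$intensity
  floor_abs <- rel_floor * max(abs(y))

  label <- "mixed_turn"
  if (max(abs(y)) > 0) {
    mins <- local_minima(y)
    mins <- mins[y[mins] < -floor_abs]
    min_pos <- x[mins]
    pos_195_205 <- max(y[x >= 195 & x <= 205]) > floor_abs
    neg_215_225 <- any(min_pos >= 215 & min_pos <= 225)
    neg_208 <- any(abs(min_pos - 208) <= 4)
    neg_220_225 <- any(min_pos >= 219 & min_pos <= 226)
    # dominant minimum overall
    dom <- if (length(mins)) x[mins[which.min(y[mins])]] else NA_real_
    if (neg_215_225 && pos_195_205) {
      label <- "beta_sheet"
    } else if (neg_208 && neg_220_225 && !pos_195_205) {
      label <- "helix"
    } else if (!is.na(dom) && dom >= 195 && dom <= 203) {
      label <- "unordered"
    }
  }
  dplyr::bind_cols(spectra[1, SPECTRUM_KEYS], tibble::tibble(label = label))
}
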