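#' Concentration-corrected mixture fluorescence
#'
#' Fluorescence attributable to parent-peptide fibrils in a
#' parent-plus-fragment mixture: the fragment's own contribution, measured on
#' the pure fragment at its reference concentration, is scaled by the
#' concentration ratio (`correction`, default 0.7 for 70 uM in the mixture
#' against a 100 uM pure-fragment reference, assuming fluorescence linear in
#' peptide concentration) and subtracted:
#' \deqn{F^{*} = F_{tot} - c \cdot F_{frag}.}
#'
#' @param f_tot Plateau ThT value of the mixture (a.u.).
#' @param f_frag Plateau ThT value of the fragment alone (a.u.).
#' @param correction Concentration-correction factor in (0, 1\].
#' @return `f_tot - correction * f_frag`; may be negative (flag downstream,
#'   never clamped).
#' @export
#' @examples
#' corrected_mixture_signal(50, 30) # 29
corrected_mixture_signal <- function(f_tot, f_frag, correction = 0.7) {
  stopifnot(is.numeric(f_tot), is.numeric(f_frag))
  if (any(correction <= 0 | correction > 1)) {
    abort("`correction` must lie in (0, 1].")
  }
  f_tot - correction * f_frag
}

#' Inhibition percentage of parent fibrillogenesis
#'
#' The screening statistic \deqn{IP = (1 - F^{*}/F_0) \times 100\%,} where
#' \eqn{F^{*}} is the concentration-corrected mixture fluorescence
#' ([corrected_mixture_signal()]) and \eqn{F_0} the plateau ThT fluorescence
#' of the parent peptide alone. Values below 0 (enhancement) or above 100
#' (over-correction) are returned as-is; clamping would hide assay
#' anomalies.
#'
#' @inheritParams corrected_mixture_signal
#' @param f0 Plateau ThT value of the parent alone (a.u.), > 0.
#' @return Inhibition percentage(s).
#' @export
#' @examples
#' inhibition_percentage(f_tot = 50, f_frag = 30, f0 = 100) # 71
inhibition_percentage <- function(f_tot, f_frag, f0, correction = 0.7) {
  stopifnot(is.numeric(f0))
  if (any(f0 <= 0)) abort("`f0` must be positive.")
  f_star <- corrected_mixture_signal(f_tot, f_frag, correction)
  (1 - f_star / f0) * 100
}

#' Full inhibition-percentage pipeline from time courses
#'
#' Applies the plateau reduction ([window_mean()]) over `window` hours to the
#' mixture, fragment-alone and parent-alone ThT time courses, then computes
#' the inhibition percentage. When the three series carry the same number of
#' replicates, IP is computed per replicate index and summarised as mean and
#' across-replicate SD; otherwise grand means are used and the spread is
#' propagated from the parent/mixture window SDs.
#'
#' @param mix,frag,parent Time-course tibbles (see [tht_timecourse()]) for
#'   the parent+fragment mixture, the fragment alone, and the parent alone.
#' @param window Plateau window in hours, default `c(32, 48)`.
#' @param correction Concentration-correction factor, default 0.7.
#' @return An object of class `"inhibition_result"`: list with `ip` (mean
#'   IP, percent), `sd`, `per_replicate` (tibble or `NULL`), `n`, `flags`
#'   (character), plus the window-mean summaries of the three inputs.
#'   [tidy()][generics::tidy] and [glance()] methods are provided.
#' @export
ip_pipeline <- function(mix, frag, parent, window = c(32, 48),
                        correction = 0.7) {
  wm_mix <- window_mean(mix, window[1], window[2])
  wm_frag <- window_mean(frag, window[1], window[2])
  wm_parent <- window_mean(parent, window[1], window[2])

  paired <- wm_mix$n == wm_frag$n && wm_mix$n == wm_parent$n
  flags <- character()
  if (paired) {
    per <- tibble::tibble(
      replicate = wm_mix$per_replicate$replicate,
      ip = inhibition_percentage(
        wm_mix$per_replicate$mean,
        wm_frag$per_replicate$mean,
        wm_parent$per_replicate$mean,
        correction
      )
    )
    ip <- mean(per$ip)
    ip_sd <- if (nrow(per) > 1) sd(per$ip) else 0
    n <- nrow(per)
    if (n < 2) flags <- c(flags, "small_n")
  } else {
    per <- NULL
    ip <- inhibition_percentage(wm_mix$mean, wm_frag$mean, wm_parent$mean,
                                correction)
    # first-order propagation through IP = (1 - (F_tot - c F_frag)/F0) * 100
    f_star <- corrected_mixture_signal(wm_mix$mean, wm_frag$mean, correction)
    ip_sd <- 100 * sqrt(
      (wm_mix$sd / wm_parent$mean)^2 +
        (correction * wm_frag$sd / wm_parent$mean)^2 +
        (f_star * wm_parent$sd / wm_parent$mean^2)^2
    )
    n <- NA_integer_
    flags <- c(flags, "unpaired_replicates")
  }
  if (ip < 0) flags <- c(flags, "negative_ip")
  if (ip > 100) flags <- c(flags, "ip_above_100")
  structure(
    list(ip = ip, sd = ip_sd, per_replicate = per, n = n,
         window = window, correction = correction, flags = flags,
         inputs = list(mix = wm_mix, frag = wm_frag, parent = wm_parent)),
    class = "inhibition_result"
  )
}

#' @export
print.inhibition_result <- function(x, ...) {
  cat(sprintf("Inhibition percentage: %.1f +/- %.1f%% (window %g-%g h, correction %g)\n",
              x$ip, x$sd, x$window[1], x$window[2], x$correction))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Per-timepoint two-sample t-tests between two time courses
#'
#' At every shared time point in `[t_lo, t_hi]`, a two-tailed two-sample
#' t-test across replicates between the two groups; the per-timepoint
#' p-values are reported together with their mean and SD (the
#' "p = 0.0214 +/- 0.0084" style of summary). Student's pooled-variance test
#' is the default; set `var_equal = FALSE` for Welch. Time points where both
#' groups have zero variance give p = 1 when the means are exactly equal and
#' are otherwise flagged degenerate (p = NA).
#'
#' @param group_a,group_b Time-course tibbles with \eqn{\ge} 2 replicates at
#'   each shared time point.
#' @param t_lo,t_hi Time window in hours.
#' @param var_equal Pooled-variance (Student) test if `TRUE` (default).
#' @return A list of class `"ttest_summary"`: `per_timepoint` (tibble
#'   `time_h`, `statistic`, `df`, `p`, `degenerate`), `mean_p`, `sd_p`, `n`.
#' @export
timepoint_ttests <- function(group_a, group_b, t_lo = -Inf, t_hi = Inf,
                             var_equal = TRUE) {
  group_a <- validate_timecourse(group_a, "group_a")
  group_b <- validate_timecourse(group_b, "group_b")
  ta <- unique(group_a$time_h[group_a$time_h >= t_lo & group_a$time_h <= t_hi])
  tb <- unique(group_b$time_h[group_b$time_h >= t_lo & group_b$time_h <= t_hi])
  shared <- sort(intersect(ta, tb))
  if (!length(shared)) abort("The two groups share no time points in the window.")
  rows <- purrr::map_dfr(shared, function(tt) {
    xa <- group_a$value[group_a$time_h == tt]
    xb <- group_b$value[group_b$time_h == tt]
    if (length(xa) < 2 || length(xb) < 2) {
      abort(sprintf("Fewer than 2 replicates at t = %g h.", tt))
    }
    if (sd(xa) == 0 && sd(xb) == 0) {
      same <- isTRUE(all.equal(mean(xa), mean(xb)))
      return(tibble::tibble(
        time_h = tt, statistic = if (same) 0 else NA_real_,
        df = NA_real_, p = if (same) 1 else NA_real_, degenerate = !same
      ))
    }
    ht <- t.test(xa, xb, var.equal = var_equal)
    tibble::tibble(time_h = tt, statistic = unname(ht$statistic),
                   df = unname(ht$parameter), p = ht$p.value,
                   degenerate = FALSE)
  })
  p_ok <- rows$p[!is.na(rows$p)]
  structure(
    list(per_timepoint = rows,
         mean_p = mean(p_ok),
         sd_p = if (length(p_ok) > 1) sd(p_ok) else 0,
         n = length(p_ok)),
    class = "ttest_summary"
  )
}

#' @export
print.ttest_summary <- function(x, ...) {
  cat(sprintf("Per-timepoint t-tests (%d time points): p = %.4g +/- %.4g\n",
              x$n, x$mean_p, x$sd_p))
  invisible(x)
}
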