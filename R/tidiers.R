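#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an inhibition result
#'
#' @param x An `"inhibition_result"` from [ip_pipeline()].
#' @param ... Unused.
#' @return Per-replicate IPs as a tibble (or the single pooled row when
#'   replicates were unpaired).
#' @method tidy inhibition_result
#' @export
tidy.inhibition_result <- function(x, ...) {
  if (!is.null(x$per_replicate)) {
    x$per_replicate
  } else {
    tibble::tibble(replicate = NA_integer_, ip = x$ip)
  }
}

#' @rdname tidy.inhibition_result
#' @return `glance()`: a one-row summary tibble with `ip`, `sd`, `n`,
#'   `window_lo`, `window_hi`, `correction`, `flags`.
#' @method glance inhibition_result
#' @export
glance.inhibition_result <- function(x, ...) {
  tibble::tibble(
    ip = x$ip, sd = x$sd, n = x$n,
    window_lo = x$window[1], window_hi = x$window[2],
    correction = x$correction,
    flags = paste(x$flags, collapse = ";")
  )
}

#' Tidy an amide-I decomposition
#'
#' @param x An `"amide_fit"` from [decompose_amide_i()].
#' @param ... Unused.
#' @return `tidy()`: the per-band fraction tibble; `glance()`: a one-row fit
#'   summary.
#' @method tidy amide_fit
#' @export
tidy.amide_fit <- function(x, ...) x$fractions

#' @rdname tidy.amide_fit
#' @method glance amide_fit
#' @export
glance.amide_fit <- function(x, ...) {
  tibble::tibble(
    sample_id = x$sample_id, time_h = x$time_h, replicate = x$replicate,
    residual = x$residual, flagged = x$flagged,
    label = classify_ftir(x)$label
  )
}

#' Tidy a per-timepoint t-test summary
#'
#' @param x A `"ttest_summary"` from [timepoint_ttests()].
#' @param ... Unused.
#' @return `tidy()`: per-timepoint statistics; `glance()`: the mean +/- SD
#'   of the p-values.
#' @method tidy ttest_summary
#' @export
tidy.ttest_summary <- function(x, ...) x$per_timepoint

#' @rdname tidy.ttest_summary
#' @method glance ttest_summary
#' @export
glance.ttest_summary <- function(x, ...) {
  tibble::tibble(mean_p = x$mean_p, sd_p = x$sd_p, n = x$n)
}

#' Tidy a window-mean summary
#'
#' @param x A `"window_mean"` from [window_mean()].
#' @param ... Unused.
#' @return `tidy()`: per-replicate window means; `glance()`: grand mean, SD
#'   and flags.
#' @method tidy window_mean
#' @export
tidy.window_mean <- function(x, ...) x$per_replicate

#' @rdname tidy.window_mean
#' @method glance window_mean
#' @export
glance.window_mean <- function(x, ...) {
  tibble::tibble(mean = x$mean, sd = x$sd, n = x$n, small_n = x$small_n,
                 window_lo = x$window[1], window_hi = x$window[2])
}
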