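# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Brute-force isoelectric point: zero crossing of the Henderson-Hasselbalch
# charge on a fine pH grid, written directly from the pKa table.
oracle_pi_grid <- function(sequence, free_termini = TRUE, step = 1e-4) {
  tab <- fragscreen::pka_bjellqvist()
  res <- strsplit(sequence, "")[[1]]
  pkas <- c()
  signs <- c()
  for (r in res) {
    if (r %in% names(tab$side)) {
      pkas <- c(pkas, tab$side[[r]])
      signs <- c(signs, tab$sign[[r]])
    }
  }
  if (free_termini) {
    nt <- tab$nterm_by_residue[res[1]]
    if (is.na(nt)) nt <- tab$nterm_default
    ct <- tab$cterm_by_residue[res[length(res)]]
    if (is.na(ct)) ct <- tab$cterm_default
    pkas <- c(pkas, nt, ct)
    signs <- c(signs, "basic", "acidic")
  }
  grid <- seq(0, 14, by = step)
  q <- rep(0, length(grid))
  for (i in seq_along(pkas)) {
    q <- q + if (signs[i] == "basic") {
      1 / (1 + 10^(grid - pkas[i]))
    } else {
      -1 / (1 + 10^(pkas[i] - grid))
    }
  }
  cross <- which(q[-length(q)] > 0 & q[-1] <= 0)[1]
  grid[cross]
}

# Savitzky-Golay smoothing by explicit local least squares: fit a degree-
# `order` polynomial to each window and take its value at the window centre.
# Interior points only; edges returned as NA.
oracle_sg_fit <- function(y, points, order) {
  h <- (points - 1) / 2
  n <- length(y)
  out <- rep(NA_real_, n)
  for (i in (h + 1):(n - h)) {
    z <- (-h):h
    X <- outer(z, 0:order, `^`)
    beta <- solve(crossprod(X), crossprod(X, y[(i - h):(i + h)]))
    out[i] <- beta[1]
  }
  out
}

# Exact two-sided permutation p-value for a difference in means.
oracle_permutation_p <- function(xa, xb) {
  pooled <- c(xa, xb)
  na <- length(xa)
  idx <- utils::combn(length(pooled), na)
  obs <- abs(mean(xa) - mean(xb))
  stats <- apply(idx, 2, function(ii) {
    abs(mean(pooled[ii]) - mean(pooled[-ii]))
  })
  mean(stats >= obs - 1e-12)
}

# Finke-Watzky two-step kinetics by numerical integration.
oracle_fw_ode <- function(times, k_n, k_e, a0) {
  rhs <- function(t, state, parms) {
    a <- state[["A"]]
    list(c(A = -parms$k_n * a - parms$k_e * a * (parms$a0 - a)))
  }
  sol <- deSolve::ode(
    y = c(A = a0), times = times, func = rhs,
    parms = list(k_n = k_n, k_e = k_e, a0 = a0),
    rtol = 1e-10, atol = 1e-12
  )
  a0 - sol[, "A"]
}

# Split a spectra tibble into one tibble per acquisition time (input order).
split_spectra_for_test <- function(s) {
  split(s, factor(s$time_h, levels = unique(s$time_h)))
}
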