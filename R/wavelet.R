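#' Morlet continuous wavelet transform scalogram
#'
#' FFT-based continuous wavelet transform with the analytic Morlet
#' wavelet (center frequency `omega0 = 6` by default), evaluated on
#' log-spaced scales mapped to periods via
#' `p = 4*pi*s / (omega0 + sqrt(2 + omega0^2))`. Amplitudes `|W|` are
#' reported in decibels relative to the scalogram maximum (so the global
#' maximum sits at 0 dB and the display is invariant to rescaling the
#' input). The cone of influence marks coefficients within one e-folding
#' distance `sqrt(2)*s` of either record edge, where edge effects make
#' them unreliable. Missing bins are linearly interpolated first (and
#' counted in attribute `"n_interpolated"` of the input interpolation).
#'
#' @param series A `uniform_series`; typically seven consecutive days of
#'   activity.
#' @param band Period band `c(min_hr, max_hr)` to analyze (default
#'   `c(1, 12)`, the ultradian range).
#' @param voices Scales per octave (default 32, giving ~2% period
#'   resolution).
#' @param omega0 Morlet center frequency (default 6).
#' @return An object of class `scalogram`: `times` (hr), `periods` (hr,
#'   increasing), `amp_db` (periods x times matrix, all <= 0),
#'   `coi_mask` (same shape, `TRUE` where edge-affected), `omega0`.
#' @export
compute_cwt <- function(series, band = c(1, 12), voices = 32, omega0 = 6) {
  if (band[2] > series_span(series) / 2)
    stop("band maximum exceeds half the record span")
  if (band[1] <= 2 * series$dt)
    stop("band minimum must exceed 2*dt")
  series <- interpolate_missing(series)
  x <- series$values - mean(series$values)
  n <- length(x)
  dt <- series$dt
  npad <- 2^ceiling(log2(n))             # zero-pad to a power of two
  xh <- stats::fft(c(x, rep(0, npad - n)))
  ff <- 4 * pi / (omega0 + sqrt(2 + omega0^2))   # Fourier factor
  n_oct <- log2(band[2] / band[1])
  periods <- band[1] * 2^(seq(0, n_oct, by = 1 / voices))
  scales <- periods / ff
  k <- c(0:(npad / 2), -((npad / 2 - 1):1)) * (2 * pi / (npad * dt))
  pos <- k > 0
  amp <- matrix(0, nrow = length(periods), ncol = n)
  norm0 <- pi^(-0.25)
  for (j in seq_along(scales)) {
    s <- scales[j]
    psi <- numeric(npad)
    psi[pos] <- norm0 * sqrt(2 * pi * s / dt) *
      exp(-0.5 * (s * k[pos] - omega0)^2)
    w <- stats::fft(xh * psi, inverse = TRUE) / npad
    amp[j, ] <- Mod(w[1:n])
  }
  t <- series_times(series)
  edge <- pmin(t - t[1], t[n] - t)
  coi <- outer(sqrt(2) * scales, edge, ">")
  mx <- max(amp)
  amp_db <- if (mx > 0) 20 * log10(pmax(amp, mx * 1e-12) / mx) else
    matrix(-Inf, nrow(amp), ncol(amp))
  structure(list(times = t, periods = periods, amp_db = amp_db,
                 coi_mask = coi, omega0 = omega0),
            class = "scalogram")
}

#' @export
print.scalogram <- function(x, ...) {
  cat(sprintf(
    "<scalogram: %d periods in [%.3g, %.3g] hr x %d times, omega0=%g>\n",
    length(x$periods), min(x$periods), max(x$periods), length(x$times),
    x$omega0))
  invisible(x)
}

#' Extract the amplitude ridge from a scalogram
#'
#' The ridge is the path of maximal wavelet amplitude across periods over
#' time — its mean and standard deviation summarize each animal's
#' dominant ultradian period and its intra-animal variability. By default
#' each time point's argmax is taken independently; a positive
#' `jump_penalty` (dB per voice) switches to a dynamic-programming ridge
#' that discourages implausible scale jumps between adjacent time points.
#' Edge-affected (cone-of-influence) points keep their ridge value but
#' are flagged and excluded from summary statistics.
#'
#' @param scal A `scalogram`.
#' @param jump_penalty Continuity penalty in dB per voice step
#'   (default 0 = plain argmax).
#' @return An object of class `ridge_trace`: `times`, `ridge_periods`,
#'   `in_coi` (logical), `mean_period`, `sd_period` (over non-COI points).
#' @export
extract_ridge <- function(scal, jump_penalty = 0) {
  A <- scal$amp_db
  np <- nrow(A); nt <- ncol(A)
  if (jump_penalty <= 0) {
    idx <- max.col(t(A), ties.method = "first")
  } else {
    # Viterbi over period indices with |voice jump| * penalty cost
    cost <- -A
    D <- jump_penalty * abs(outer(seq_len(np), seq_len(np), "-"))
    acc <- cost[, 1]
    back <- matrix(0L, np, nt)
    for (i in 2:nt) {
      M <- acc + D                       # np x np: prev state x new state
      j <- max.col(t(-M), ties.method = "first")
      acc <- M[cbind(j, seq_len(np))] + cost[, i]
      back[, i] <- j
    }
    idx <- integer(nt)
    idx[nt] <- which.min(acc)
    for (i in nt:2) idx[i - 1] <- back[idx[i], i]
  }
  rp <- scal$periods[idx]
  in_coi <- scal$coi_mask[cbind(idx, seq_len(nt))]
  ok <- !in_coi
  structure(list(times = scal$times, ridge_periods = rp, in_coi = in_coi,
                 mean_period = if (any(ok)) mean(rp[ok]) else NA_real_,
                 sd_period = if (sum(ok) > 1) stats::sd(rp[ok]) else NA_real_),
            class = "ridge_trace")
}

#' @export
print.ridge_trace <- function(x, ...) {
  cat(sprintf(
    "<ridge: mean period %.3g hr, SD %.3g hr over %d non-COI points>\n",
    x$mean_period, x$sd_period, sum(!x$in_coi)))
  invisible(x)
}

#' Mean and SD of the ridge period outside the cone of influence
#'
#' @param ridge A `ridge_trace` with at least 100 usable (non-COI) points.
#' @return Named numeric vector `c(mean_hr, sd_hr)`.
#' @export
ridge_period_stats <- function(ridge) {
  ok <- !ridge$in_coi
  if (sum(ok) < 100L)
    stop("need at least 100 ridge points outside the cone of influence")
  c(mean_hr = mean(ridge$ridge_periods[ok]),
    sd_hr = stats::sd(ridge$ridge_periods[ok]))
}
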