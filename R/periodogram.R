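#' Lomb-Scargle periodogram of a binned series
#'
#' Computes the standard-normalized Lomb-Scargle periodogram on a grid of
#' trial periods. Missing bins are simply omitted — the reason this
#' estimator suits intermittently expressed ultradian rhythms: it
#' tolerates gaps and noisy data without imputation. Power at angular
#' frequency `w` uses the phase offset `tau` chosen so the sine and
#' cosine regressors decouple, normalized by the sample variance of the
#' non-missing points, so on gap-free data it coincides with the
#' classical periodogram at the Fourier frequencies.
#'
#' The significance threshold at level `alpha` uses the
#' Horne-Baliunas form `z = -log(1 - (1 - alpha)^(1/M))` with `M` the
#' number of grid frequencies.
#'
#' The per-period amplitude estimate is
#' `sqrt(4 * power * var / n_eff)`, which returns the amplitude of a pure
#' sinusoid exactly.
#'
#' @param series A `uniform_series` with at least 16 non-missing bins.
#' @param band Period band `c(min_hr, max_hr)` to search (default
#'   `c(1, 40)`). The minimum must exceed `2*dt`.
#' @param grid_step Period grid step in hours above `fine_below`
#'   (default 0.1).
#' @param fine_step Finer step used below `fine_below` hours (default
#'   0.02) for ultradian precision.
#' @param fine_below Period below which `fine_step` applies (default 5).
#' @param alpha Significance level for the threshold (default 0.01).
#' @param periods Optional explicit period grid (hours); overrides the
#'   band/step arguments.
#' @return An object of class `periodogram`: list with `periods`, `power`,
#'   `amplitude`, `alpha`, `threshold`, `n_eff`, `m_indep`.
#' @export
compute_lomb_scargle <- function(series, band = c(1, 40), grid_step = 0.1,
                                 fine_step = 0.02, fine_below = 5,
                                 alpha = 0.01, periods = NULL) {
  keep <- !series$missing_mask
  n_eff <- sum(keep)
  if (n_eff < 16L) stop("need at least 16 non-missing samples")
  if (is.null(periods)) {
    if (band[1] <= 2 * series$dt)
      stop("band minimum must exceed 2*dt (Nyquist)")
    if (band[2] <= band[1]) stop("band must be increasing")
    periods <- period_grid(band, grid_step, fine_step, fine_below)
  } else {
    if (min(periods) <= 2 * series$dt)
      stop("period grid extends below the Nyquist period 2*dt")
    periods <- sort(unique(as.numeric(periods)))
  }
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  t <- series_times(series)[keep]
  y <- series$values[keep]
  v <- stats::var(y)
  pw <- if (v <= 0) rep(0, length(periods)) else
    .ls_power(t, y - mean(y), 2 * pi / periods) / v
  m <- length(periods)
  thr <- -log(1 - (1 - alpha)^(1 / m))
  amp <- sqrt(pmax(4 * pw * v / n_eff, 0))
  structure(list(periods = periods, power = pw, amplitude = amp,
                 alpha = alpha, threshold = thr, n_eff = n_eff,
                 m_indep = m),
            class = "periodogram")
}

# vectorized un-normalized LS power (divide by variance outside);
# w = angular frequencies, yc = centered values
.ls_power <- function(t, yc, w) {
  TW <- outer(t, w)                      # n x m
  CO <- cos(TW); SI <- sin(TW)
  c2 <- colSums(CO^2 - SI^2)             # sum cos(2wt)
  s2 <- colSums(2 * CO * SI)             # sum sin(2wt)
  wt <- 0.5 * atan2(s2, c2)              # w * tau
  cwt <- cos(wt); swt <- sin(wt)
  # cos(w(t - tau)) = cos(wt)cos(wtau) + sin(wt)sin(wtau)
  CT <- sweep(CO, 2, cwt, "*") + sweep(SI, 2, swt, "*")
  ST <- sweep(SI, 2, cwt, "*") - sweep(CO, 2, swt, "*")
  a <- colSums(yc * CT); b <- colSums(yc * ST)
  cc <- colSums(CT^2);  ss <- colSums(ST^2)
  0.5 * (a^2 / cc + b^2 / ss)
}

#' Default period grid
#'
#' Uniform in period: `grid_step` spacing over the band, refined to
#' `fine_step` below `fine_below` hours.
#'
#' @inheritParams compute_lomb_scargle
#' @return Increasing numeric vector of periods, hours.
#' @export
period_grid <- function(band, grid_step = 0.1, fine_step = 0.02,
                        fine_below = 5) {
  lo <- band[1]; hi <- band[2]
  coarse <- seq(max(lo, fine_below), hi, by = grid_step)
  if (lo >= fine_below) return(coarse)
  fine <- seq(lo, min(hi, fine_below), by = fine_step)
  sort(unique(c(fine, coarse)))
}

#' @export
print.periodogram <- function(x, ...) {
  cat(sprintf(
    "<periodogram: %d periods in [%.3g, %.3g] hr, alpha=%g, threshold=%.3g, n_eff=%d>\n",
    length(x$periods), min(x$periods), max(x$periods), x$alpha,
    x$threshold, x$n_eff))
  invisible(x)
}

#' Call the dominant period from a periodogram
#'
#' Returns the highest local maximum above the significance threshold
#' (`alpha` level fixed when the periodogram was computed). Absence of a
#' significant peak is a valid outcome (`significant = FALSE`, `tau = NA`),
#' not an error. With `validate_harmonics = TRUE` the power at half and
#' double the called period (within one grid step) is compared against
#' the peak and the corresponding flags set when either exceeds it — an
#' automated stand-in for visual actogram confirmation of harmonics.
#' `sidelobe_suspect` is set when another significant local maximum lies
#' within the spectral main-lobe width of the called peak.
#'
#' @param pg A `periodogram`.
#' @param validate_harmonics Logical (default `TRUE`).
#' @param span_hr Record span used for the main-lobe width in the
#'   side-lobe check; taken from `1.5/span` in frequency when supplied.
#' @param band Optional `c(min_hr, max_hr)` restricting where the peak
#'   may be called; harmonic vetting still consults the full grid, so a
#'   harmonic called inside the band is flagged against its fundamental
#'   outside it.
#' @return An object of class `period_estimate`: `tau`, `peak_power`,
#'   `significant`, `harmonic_flags` (character vector).
#' @export
estimate_period <- function(pg, validate_harmonics = TRUE, span_hr = NULL,
                            band = NULL) {
  p <- pg$periods; pw <- pg$power
  m <- length(p)
  loc <- which(pw >= pg$threshold &
               pw >= c(-Inf, pw[-m]) & pw >= c(pw[-1], -Inf))
  if (!is.null(band))
    loc <- loc[p[loc] >= band[1] & p[loc] <= band[2]]
  if (!length(loc)) {
    return(structure(list(tau = NA_real_, peak_power = max(pw),
                          significant = FALSE,
                          harmonic_flags = character(0)),
                     class = "period_estimate"))
  }
  best <- loc[which.max(pw[loc])]
  tau <- p[best]; peak <- pw[best]
  flags <- character(0)
  if (validate_harmonics) {
    pow_near <- function(target) {
      step <- .grid_step_at(p, target)
      sel <- abs(p - target) <= step + 1e-12
      if (any(sel)) max(pw[sel]) else NA_real_
    }
    ph <- pow_near(tau / 2); pd <- pow_near(2 * tau)
    if (is.finite(ph) && ph > peak) flags <- c(flags, "half_period_stronger")
    if (is.finite(pd) && pd > peak) flags <- c(flags, "double_period_stronger")
    if (!is.null(span_hr)) {
      lobe <- 1.5 / span_hr              # main-lobe half width, cycles/hr
      others <- setdiff(loc, best)
      if (length(others) &&
          any(abs(1 / p[others] - 1 / tau) < lobe & p[others] != tau))
        flags <- c(flags, "sidelobe_suspect")
    }
  }
  structure(list(tau = tau, peak_power = peak, significant = TRUE,
                 harmonic_flags = flags),
            class = "period_estimate")
}

# local grid spacing around a target period
.grid_step_at <- function(p, target) {
  i <- which.min(abs(p - target))
  if (i == 1) p[2] - p[1]
  else if (i == length(p)) p[i] - p[i - 1]
  else max(p[i] - p[i - 1], p[i + 1] - p[i])
}

#' @export
print.period_estimate <- function(x, ...) {
  if (x$significant)
    cat(sprintf("<period_estimate: tau = %.3g hr, power = %.3g%s>\n",
                x$tau, x$peak_power,
                if (length(x$harmonic_flags))
                  paste0(", flags: ",
                         paste(x$harmonic_flags, collapse = ",")) else ""))
  else cat("<period_estimate: no significant period>\n")
  invisible(x)
}

#' Amplitude spectral density in a period band, as a percentage
#'
#' Trapezoidal area under the amplitude-vs-period curve restricted to
#' significant grid points (power at or above the periodogram's
#' threshold) within `band`, divided by the same significant area over
#' the periodogram's full range, times 100. Quantifies what fraction of
#' the significant rhythmic content falls in, e.g., the ultradian
#' 2-8 hr band. Non-significant grid points contribute zero amplitude to
#' both integrals. Returns 0 with attribute `empty_spectrum = TRUE` when
#' nothing is significant anywhere.
#'
#' @param pg A `periodogram` covering the full normalization range
#'   (typically up to 40 hr).
#' @param band Period band `c(min_hr, max_hr)`.
#' @param use_amplitude Integrate the derived amplitude (default) or raw
#'   power when `FALSE`.
#' @return Percentage in `[0, 100]`.
#' @export
amplitude_spectral_density <- function(pg, band, use_amplitude = TRUE) {
  if (band[1] < min(pg$periods) - 1e-9 || band[2] > max(pg$periods) + 1e-9)
    stop("band outside the periodogram's period range")
  yv <- if (use_amplitude) pg$amplitude else pg$power
  sig <- pg$power >= pg$threshold
  dens <- ifelse(sig, yv, 0)
  total <- .trapz(pg$periods, dens)
  if (total <= 0)
    return(structure(0, empty_spectrum = TRUE))
  inb <- pg$periods >= band[1] & pg$periods <= band[2]
  in_band <- .trapz(pg$periods[inb], dens[inb])
  structure(100 * in_band / total, empty_spectrum = FALSE)
}

.trapz <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' Circadian-arrhythmia screen
#'
#' `TRUE` (arrhythmic) iff the Lomb-Scargle periodogram shows no
#' significant peak at `alpha = 0.01` anywhere in the circadian 20-28 hr
#' band — the inclusion criterion used to verify complete SCN lesions
#' from at least seven days of recording.
#'
#' @param series A `uniform_series` spanning at least 7 days.
#' @param alpha Significance level (default 0.01).
#' @return Logical flag.
#' @export
circadian_arrhythmia_screen <- function(series, alpha = 0.01) {
  if (series_span(series) < 7 * 24)
    stop("need at least 7 days of data for the circadian screen")
  pg <- compute_lomb_scargle(series, band = c(20, 28), grid_step = 0.1,
                             alpha = alpha)
  est <- estimate_period(pg, validate_harmonics = FALSE)
  !est$significant
}
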