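# fixtures built in code: sinusoid series, oracle implementations

# gap-free sinusoid-plus-offset series
make_cosine_series <- function(period = 4, amp = 1, mesor = 3,
                               span = 168, dt = 0.1, phase = 0,
                               noise_sd = 0, kind = "temperature",
                               seed = NULL) {
  t <- seq(0, span - dt, by = dt)
  y <- mesor + amp * cos(2 * pi * t / period - phase)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + rnorm(length(t), 0, noise_sd)
  }
  uniform_series(y, dt = dt, kind = kind)
}

# classical (Schuster) periodogram of the centered series, normalized by
# the sample variance -- the gap-free oracle for Lomb-Scargle at Fourier
# frequencies
classical_periodogram <- function(series, periods) {
  keep <- !series$missing_mask
  t <- series_times(series)[keep]
  y <- series$values[keep]
  yc <- y - mean(y)
  v <- var(y)
  n <- length(y)
  vapply(2 * pi / periods, function(w) {
    (sum(yc * cos(w * t))^2 + sum(yc * sin(w * t))^2) / (n * v)
  }, numeric(1))
}

# Fourier-frequency period grid of a gap-free series within a band
fourier_periods <- function(series, band) {
  n <- length(series$values)
  Tspan <- n * series$dt
  p <- Tspan / (1:(n %/% 2 - 1))
  sort(p[p >= band[1] & p <= band[2]])
}

# brute-force coarse-to-fine grid search oracle for the cosinor fit,
# independent of the linear-regression implementation
grid_cosinor_oracle <- function(series, tau, n_iter = 6) {
  t <- series_times(series)
  y <- series$values
  sse_of <- function(m, a, phi)
    sum((y - (m + a * cos(2 * pi * t / tau - phi)))^2)
  m_rng <- range(y); a_rng <- c(0, diff(range(y))); p_rng <- c(0, 2 * pi)
  best <- NULL
  for (it in seq_len(n_iter)) {
    ms <- seq(m_rng[1], m_rng[2], length.out = 13)
    as <- seq(a_rng[1], a_rng[2], length.out = 13)
    ps <- seq(p_rng[1], p_rng[2], length.out = 25)
    g <- expand.grid(m = ms, a = as, p = ps)
    sse <- mapply(sse_of, g$m, g$a, g$p)
    best <- g[which.min(sse), ]
    dm <- diff(m_rng) / 6; da <- diff(a_rng) / 6; dp <- diff(p_rng) / 6
    m_rng <- c(best$m - dm, best$m + dm)
    a_rng <- c(max(0, best$a - da), best$a + da)
    p_rng <- c(best$p - dp, best$p + dp)
  }
  list(mesor = best$m, amplitude = best$a,
       acrophase = best$p %% (2 * pi))
}

# analytic two-pass gain of a digital Butterworth low-pass designed by
# bilinear transform: closed form in the warped frequency ratio
analytic_butter_gain2 <- function(period_hr, dt, cutoff_hr, order) {
  ratio <- tan(pi * dt / period_hr) / tan(pi * dt / cutoff_hr)
  1 / (1 + ratio^(2 * order))        # two passes = |H|^2
}

# amplitude of a sinusoid of known period in a series, by least squares
# on the central portion (edges trimmed)
fitted_amplitude <- function(series, period, trim = 0.1) {
  n <- length(series$values)
  sel <- seq(floor(n * trim) + 1, ceiling(n * (1 - trim)))
  t <- series_times(series)[sel]
  y <- series$values[sel]
  X <- cbind(1, cos(2 * pi * t / period), sin(2 * pi * t / period))
  b <- qr.coef(qr(X), y)
  sqrt(b[2]^2 + b[3]^2)
}

# peak-lag of the cross-correlation of two equal-length vectors; a fixed
# central window of x slides along y so edge transients do not bias the
# comparison across lags
xcorr_peak_lag <- function(x, y, max_lag = 50) {
  n <- length(x)
  trim <- max(max_lag, floor(n * 0.1))
  i <- (trim + 1):(n - trim)
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(L) cor(x[i], y[i + L]), numeric(1))
  # a periodic signal's cross-correlation peaks at every period multiple;
  # among ties, report the lag closest to zero
  ties <- lags[cc >= max(cc) - 1e-6]
  ties[which.min(abs(ties))]
}
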