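test_that("Lomb-Scargle equals the classical periodogram on gap-free data", {
  s <- make_cosine_series(period = 4, amp = 1, mesor = 3, span = 168,
                          dt = 0.1, noise_sd = 0.3, seed = 11)
  periods <- fourier_periods(s, c(1, 40))
  pg <- compute_lomb_scargle(s, periods = periods)
  oracle <- classical_periodogram(s, pg$periods)
  expect_lt(max(abs(pg$power - oracle)) / max(oracle), 1e-9)
  # power peaks at the grid period nearest 4 hr
  expect_equal(pg$periods[which.max(pg$power)], 4, tolerance = 0.05)
})

test_that("amplitude estimate returns a pure sinusoid's amplitude", {
  s <- make_cosine_series(period = 4, amp = 2.5, span = 168, dt = 0.1)
  pg <- compute_lomb_scargle(s, periods = fourier_periods(s, c(2, 8)))
  expect_equal(max(pg$amplitude), 2.5, tolerance = 0.01)
})

test_that("constant series carries no power; masked gaps are tolerated", {
  const <- uniform_series(rep(5, 400), dt = 0.1, kind = "activity")
  pg <- compute_lomb_scargle(const, band = c(1, 12))
  expect_lte(max(pg$power), 1e-12)
  # 20% of bins masked at random: peak stays at 4 hr
  set.seed(5)
  s <- make_cosine_series(period = 4, amp = 1, mesor = 3, span = 168,
                          dt = 0.1, noise_sd = 0.3, seed = 5)
  drop <- sample(length(s$values), round(0.2 * length(s$values)))
  s$missing_mask[drop] <- TRUE
  pg2 <- compute_lomb_scargle(s, band = c(1, 12))
  expect_equal(pg2$n_eff, length(s$values) - length(drop))
  expect_equal(pg2$periods[which.max(pg2$power)], 4, tolerance = 0.05)
})

test_that("period calling is scale invariant and absence of rhythm is valid", {
  set.seed(9)
  noise <- uniform_series(rnorm(1680, 10, 1), dt = 0.1,
                          kind = "temperature")
  est <- estimate_period(compute_lomb_scargle(noise, band = c(1, 12)))
  expect_false(est$significant)
  expect_true(is.na(est$tau))
  s <- make_cosine_series(period = 4, amp = 1, mesor = 3, span = 168,
                          noise_sd = 0.5, seed = 2)
  tau1 <- estimate_period(compute_lomb_scargle(s, band = c(1, 12)))$tau
  s2 <- s; s2$values <- s$values * 37.5
  tau2 <- estimate_period(compute_lomb_scargle(s2, band = c(1, 12)))$tau
  expect_identical(tau1, tau2)
})

test_that("harmonic vetting: fundamental wins, excluded fundamental is flagged", {
  # 30%-duty pulse train of period 8 hr: strong 4-hr harmonic
  t <- seq(0, 168 - 0.1, by = 0.1)
  set.seed(3)
  y <- ifelse((t %% 8) < 2.4, 40, 0) + rpois(length(t), 2)
  s <- uniform_series(y, dt = 0.1, kind = "activity")
  pg <- compute_lomb_scargle(s, band = c(1, 40))
  est <- estimate_period(pg)
  expect_equal(est$tau, 8, tolerance = 0.1)
  expect_false("double_period_stronger" %in% est$harmonic_flags)
  # restrict the peak search below the fundamental: harmonic called, flagged
  est2 <- estimate_period(pg, band = c(1, 6))
  expect_equal(est2$tau, 4, tolerance = 0.1)
  expect_true("double_period_stronger" %in% est2$harmonic_flags)
})

test_that("ASD is 100% when all significant density lies in band, less otherwise", {
  s <- make_cosine_series(period = 4, amp = 1, mesor = 2, span = 168,
                          dt = 0.1)
  pg <- compute_lomb_scargle(s, band = c(1, 40))
  asd <- amplitude_spectral_density(pg, c(2, 8))
  expect_equal(as.numeric(asd), 100)
  expect_false(attr(asd, "empty_spectrum"))
  # equal-amplitude 24-hr component strictly decreases the 2-8-hr share
  s2 <- s
  t <- series_times(s)
  s2$values <- s$values + cos(2 * pi * t / 24)
  pg2 <- compute_lomb_scargle(s2, band = c(1, 40))
  asd2 <- amplitude_spectral_density(pg2, c(2, 8))
  expect_lt(as.numeric(asd2), as.numeric(asd))
  # full-range ASD is 100% whenever anything is significant
  expect_equal(as.numeric(amplitude_spectral_density(pg2, c(1, 40))), 100)
  # no significant periodicity: 0% with the empty-spectrum flag
  set.seed(8)
  noise <- uniform_series(rnorm(1680, 5, 1), dt = 0.1,
                          kind = "temperature")
  pgn <- compute_lomb_scargle(noise, band = c(1, 40))
  if (max(pgn$power) < pgn$threshold) {
    asd0 <- amplitude_spectral_density(pgn, c(2, 8))
    expect_equal(as.numeric(asd0), 0)
    expect_true(attr(asd0, "empty_spectrum"))
  }
  expect_error(amplitude_spectral_density(pg, c(0.1, 8)), "outside")
})

test_that("circadian-arrhythmia screen separates gated from clockless animals", {
  lesioned <- simulate_activity(duo_config(seed = 31))
  expect_true(circadian_arrhythmia_screen(lesioned$record$activity))
  intact <- simulate_activity(duo_config(circadian_gate = "ld_mask",
                                         seed = 32))
  expect_false(circadian_arrhythmia_screen(intact$record$activity))
  # a 22-hr rhythm lies inside the 20-28-hr band
  s22 <- make_cosine_series(period = 22, amp = 5, mesor = 10, span = 168,
                            noise_sd = 1, seed = 4, kind = "activity")
  expect_false(circadian_arrhythmia_screen(s22))
  expect_error(circadian_arrhythmia_screen(make_cosine_series(span = 100)),
               "7 days")
})
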