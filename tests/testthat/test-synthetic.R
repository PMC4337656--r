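test_that("simulation is deterministic under a fixed seed", {
  a <- simulate_activity(duo_config(seed = 123))
  b <- simulate_activity(duo_config(seed = 123))
  expect_identical(a$record$activity$values, b$record$activity$values)
  expect_identical(a$truth$periods, b$truth$periods)
  c <- simulate_activity(duo_config(seed = 124))
  expect_false(identical(a$record$activity$values,
                         c$record$activity$values))
  # the generator does not disturb the caller's RNG stream
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(simulate_activity(duo_config(seed = 9)))
  x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("period law is exact with zero jitter and linear in tone", {
  sim <- simulate_activity(duo_config(tone = 1.5, cycle_jitter_sd = 0,
                                      seed = 2))
  expect_true(all(abs(sim$truth$periods - 6) < 1e-12))
  expect_equal(duo_period(duo_config(tone = 1)), 4)
  expect_equal(duo_period(duo_config(tone = 3)), 12)
  expect_error(duo_config(tone = 0, period_slope = 4, tau0 = 0.1),
               "tau")
})

test_that("LD masking suppresses light-phase activity", {
  sim <- simulate_activity(duo_config(circadian_gate = "ld_mask",
                                      gate_depth = 0.1, seed = 33,
                                      duration = 10 * 24))
  v <- sim$record$activity$values
  tod <- series_times(sim$record$activity) %% 24
  light <- mean(v[tod < 12]); dark <- mean(v[tod >= 12])
  expect_lte(light, 0.15 * dark)
})

test_that("coupled dopamine profile peaks with the activity bouts", {
  sim <- simulate_activity(duo_config(cycle_jitter_sd = 0, seed = 3))
  cfg <- da_coupling_config(noise_sd = 0, phase_offset = 0)
  prof <- simulate_da_profile(sim$truth, cfg, start_hr = 20)
  # DA maximum within one sample of a bout peak (integer phase)
  phi <- sim$truth$phase_at(prof$sample_times)
  imax <- which.max(prof$concentrations)
  dist <- abs(phi[imax] - round(phi[imax]))
  expect_lte(dist, cfg$interval / duo_period(sim$truth$config))
  # sampling over >= 3 full cycles averages to mean_da within 5%
  cfg2 <- da_coupling_config(noise_sd = 0, n_samples = 36)
  prof2 <- simulate_da_profile(sim$truth, cfg2, start_hr = 20)
  expect_equal(mean(prof2$concentrations), cfg2$mean_da,
               tolerance = 0.05)
  expect_error(simulate_da_profile(sim$truth, cfg, start_hr = 167),
               "outside")
})

test_that("cohort generation is reproducible and carries a truth table", {
  coh1 <- simulate_cohort(seed = 5)
  coh2 <- simulate_cohort(seed = 5)
  expect_identical(coh1$truth_table, coh2$truth_table)
  expect_identical(coh1$animals[[3]]$record$activity$values,
                   coh2$animals[[3]]$record$activity$values)
  expect_equal(nrow(coh1$truth_table), 8)
  expect_equal(coh1$truth_table$tau_true,
               4 + 4 * (coh1$truth_table$tone - 1))
  expect_error(simulate_cohort(n_animals = 2), "3 animals")
  # degenerate tone range: near-zero regression slope
  cohd <- simulate_cohort(tone_range = c(1, 1), seed = 6)
  taus <- vapply(cohd$animals, function(a)
    estimate_period(compute_lomb_scargle(a$record$activity,
                                         band = c(1, 12)))$tau,
    numeric(1))
  expect_lt(diff(range(taus)), 0.5)
})

test_that("dose-tone maps are monotone with the documented directions", {
  expect_equal(dose_to_tone("meth", 0), 1)
  expect_equal(dose_to_tone("amphetamine", 0), 1)
  expect_equal(dose_to_tone("haloperidol", 0), 1)
  expect_gt(dose_to_tone("meth", 100), dose_to_tone("meth", 25))
  expect_gt(dose_to_tone("meth", 25), 1)
  # amphetamine raises tone with a smaller gain than meth
  expect_lt(dose_to_tone("amphetamine", 50), dose_to_tone("meth", 50))
  expect_gt(dose_to_tone("amphetamine", 50), 1)
  # haloperidol lowers tone toward a positive floor
  hal <- dose_to_tone("haloperidol", c(5, 25, 100, 1e6))
  expect_true(all(diff(hal) < 0))
  expect_true(all(hal < 1 & hal > 0))
  expect_error(dose_to_tone("meth", -1), "non-negative")
})

test_that("haloperidol-driven tone reduction shortens the called period", {
  tone_hal <- dose_to_tone("haloperidol", 50)
  sim <- simulate_activity(duo_config(tone = tone_hal, seed = 8))
  est <- estimate_period(compute_lomb_scargle(sim$record$activity,
                                              band = c(1, 12)))
  expect_true(est$significant)
  expect_lt(est$tau, 4)
  expect_equal(est$tau, 4 + 4 * (tone_hal - 1), tolerance = 0.2)
})
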