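test_that("cosinor recovers noiseless parameters exactly", {
  t <- seq(0, 20 - 1/3, by = 1/3)
  y <- 2 + 1.5 * cos(2 * pi * t / 4 - 1)
  s <- uniform_series(y, dt = 1/3, kind = "activity")
  cm <- fit_cosinor(s, 4)
  expect_equal(cm$mesor, 2, tolerance = 1e-8)
  expect_equal(cm$amplitude, 1.5, tolerance = 1e-8)
  expect_equal(cm$acrophase, 1, tolerance = 1e-8)
  expect_lt(cm$fit_sse, 1e-16)
  # constant series: zero amplitude, mesor = mean
  const <- uniform_series(rep(3.7, 60), dt = 1/3, kind = "temperature")
  cmc <- fit_cosinor(const, 4)
  expect_equal(cmc$amplitude, 0, tolerance = 1e-12)
  expect_equal(cmc$mesor, 3.7)
  expect_error(fit_cosinor(s, 25), "span")
})

test_that("noisy cosinor fits match the dense grid-search oracle", {
  for (seed in c(1, 2)) {
    set.seed(seed)
    t <- seq(0, 20 - 1/3, by = 1/3)
    y <- 5 + 2 * cos(2 * pi * t / 4.3 - 2.1) + rnorm(length(t), 0, 0.4)
    s <- uniform_series(y, dt = 1/3, kind = "activity")
    cm <- fit_cosinor(s, 4.3)
    oracle <- grid_cosinor_oracle(s, 4.3, n_iter = 14)
    expect_equal(cm$mesor, oracle$mesor, tolerance = 1e-6)
    expect_equal(cm$amplitude, oracle$amplitude, tolerance = 1e-6)
    expect_equal(cm$acrophase, oracle$acrophase, tolerance = 1e-5)
  }
})

test_that("cosinor SSE never exceeds that of the nested mesor-only model", {
  set.seed(12)
  for (i in 1:20) {
    y <- rnorm(60, 10, 2)
    s <- uniform_series(y, dt = 1/3, kind = "temperature")
    cm <- fit_cosinor(s, runif(1, 2, 10))
    expect_lte(cm$fit_sse, sum((y - mean(y))^2) + 1e-10)
  }
})

test_that("concordance SSE: perfect fit zero, antiphase matches hand formula", {
  t <- seq(0, 20 - 1/3, by = 1/3)
  y <- 10 + 4 * cos(2 * pi * t / 4)
  s <- uniform_series(y, dt = 1/3, kind = "activity")
  cm <- fit_cosinor(s, 4)
  ts <- (0:11) / 3 + 1/6
  cvals <- predict(cm, ts)
  perfect <- dialysate_profile(ts, 2 + (cvals - min(cvals)) /
                                     diff(range(cvals)))
  expect_equal(concordance_sse(cm, perfect), 0, tolerance = 1e-12)
  # antiphase profile: SSE = sum((1 - 2*c_i)^2) on the normalized scale
  cnorm <- (cvals - min(cvals)) / diff(range(cvals))
  anti <- dialysate_profile(ts, 1 - cnorm)
  expect_equal(concordance_sse(cm, anti), sum((1 - 2 * cnorm)^2),
               tolerance = 1e-10)
  # iid noise is strictly positive
  set.seed(77)
  noisy <- dialysate_profile(ts, runif(12, 1, 3))
  expect_gt(concordance_sse(cm, noisy), 0)
  flat <- dialysate_profile(ts, rep(2, 12))
  expect_error(concordance_sse(cm, flat), "flat")
})

test_that("exhaustive FDR on a length-4 profile matches direct enumeration", {
  t <- seq(0, 16 - 1, by = 1)
  y <- 5 + 2 * cos(2 * pi * t / 8)
  s <- uniform_series(y, dt = 1, kind = "activity")
  cm <- fit_cosinor(s, 8)
  ts <- c(0.5, 1.5, 2.5, 3.5)
  vals <- c(1, 3, 2, 4)
  prof <- dialysate_profile(ts, vals, interval = 1)
  res <- exhaustive_fdr(cm, prof)
  # direct enumeration, written out independently
  cz <- predict(cm, ts)
  cz <- (cz - min(cz)) / diff(range(cz))
  pz <- (vals - min(vals)) / diff(range(vals))
  perms <- as.matrix(expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 4), ]
  sse_all <- apply(perms, 1, function(o) sum((pz[o] - cz)^2))
  obs <- sum((pz - cz)^2)
  expect_equal(res$n_permutations, 24L)
  expect_equal(res$fdr_percent, 100 * mean(sse_all <= obs + 1e-9),
               tolerance = 1e-9)
  # a perfect-fit profile achieves the minimum (ties only)
  best <- dialysate_profile(ts, 1 + 2 * cz, interval = 1)
  resb <- exhaustive_fdr(cm, best)
  expect_equal(resb$fdr_percent, 100 * 1 / 24)
  # amplitude-zero cosinor: every ordering ties, FDR 100%
  cflat <- fit_cosinor(uniform_series(rep(4, 16), dt = 1,
                                      kind = "activity"), 8)
  resf <- exhaustive_fdr(cflat, prof)
  expect_equal(resf$fdr_percent, 100)
})

test_that("Monte-Carlo FDR agrees with exhaustive enumeration on n=6", {
  t <- seq(0, 20 - 1/3, by = 1/3)
  y <- 10 + 4 * cos(2 * pi * t / 4 - 0.7)
  cm <- fit_cosinor(uniform_series(y, dt = 1/3, kind = "activity"), 4)
  ts <- (0:5) / 3 + 1/6
  set.seed(42)
  vals <- 2 + 0.8 * cos(2 * pi * ts / 4 - 0.7) + rnorm(6, 0, 0.3)
  prof <- dialysate_profile(ts, pmax(vals, 0))
  ex <- exhaustive_fdr(cm, prof)
  mc <- permutation_fdr(cm, prof, n_perm = 100000, seed = 9)
  p <- ex$fdr_percent / 100
  ci_half <- 2.576 * sqrt(p * (1 - p) / 100000)
  expect_lte(abs(mc$fdr_percent / 100 - p), ci_half + 1e-9)
})

test_that("permutation FDR is invariant to affine rescaling of the profile", {
  t <- seq(0, 20 - 1/3, by = 1/3)
  y <- 10 + 4 * cos(2 * pi * t / 4)
  cm <- fit_cosinor(uniform_series(y, dt = 1/3, kind = "activity"), 4)
  ts <- (0:11) / 3 + 1/6
  set.seed(15)
  vals <- runif(12, 1, 3)
  p1 <- dialysate_profile(ts, vals)
  p2 <- dialysate_profile(ts, 3 * vals + 7)
  r1 <- permutation_fdr(cm, p1, n_perm = 2000, seed = 5)
  r2 <- permutation_fdr(cm, p2, n_perm = 2000, seed = 5)
  expect_equal(r1$fdr_percent, r2$fdr_percent)
  expect_equal(r1$observed_sse, r2$observed_sse, tolerance = 1e-10)
  # a perfect-fit profile essentially never loses to a permutation
  cz <- predict(cm, ts)
  perf <- dialysate_profile(ts, (cz - min(cz)) / diff(range(cz)) + 1)
  rp <- permutation_fdr(cm, perf, n_perm = 100000, seed = 6)
  expect_lte(rp$fdr_percent, 0.01)
})

test_that("period-tone regression recovers exact and degenerate cases", {
  da <- c(0.5, 1, 1.5, 2, 2.5)
  # exact-line fixtures make lm warn about a perfect fit; that is the point
  reg <- suppressWarnings(period_tone_regression(4 + 2 * da, da))
  expect_equal(reg$slope, 2, tolerance = 1e-10)
  expect_equal(reg$r_squared, 1, tolerance = 1e-10)
  regc <- suppressWarnings(period_tone_regression(rep(4, 5), da))
  expect_equal(regc$slope, 0, tolerance = 1e-10)
  expect_error(period_tone_regression(c(4, 5), c(1, 2)), "3 paired")
})

test_that("rhythm-adjusted mean dopamine removes partial-cycle bias", {
  ts <- (0:11) / 3 + 1/6
  tau <- 10
  # sampling window centred on a dopamine peak: worst-case raw-mean bias
  vals <- 3 * (1 + 0.3 * cos(2 * pi * (ts - 2) / tau))
  prof <- dialysate_profile(ts, vals)
  expect_gt(abs(mean(vals) - 3), 0.1)          # raw mean is biased
  expect_equal(profile_mean_da(prof, tau), 3, tolerance = 1e-6)
  expect_equal(profile_mean_da(prof, NA), mean(vals))
})
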