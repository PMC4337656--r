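#' Least-squares cosinor fit at a fixed trial period
#'
#' Fits `mesor + amplitude * cos(2*pi*t/tau - acrophase)` by ordinary
#' least squares on the regressors `{1, cos(2*pi*t/tau), sin(2*pi*t/tau)}`.
#' The trial period `tau` is supplied (typically the Lomb-Scargle call on
#' the 20-hr activity window after dialysate sampling) — the cosinor
#' estimates the rhythm's mesor (rhythm-adjusted mean), amplitude and
#' acrophase at that period, it does not search for the period.
#'
#' @param series A gap-free `uniform_series` spanning at least one period
#'   (rebin activity to the 20-min dialysate cadence first).
#' @param tau Trial period, hours.
#' @return An object of class `cosinor_model`: `tau`, `mesor`,
#'   `amplitude` (>= 0), `acrophase` (radians in `[0, 2*pi)`), `fit_sse`.
#' @export
fit_cosinor <- function(series, tau) {
  if (any(series$missing_mask))
    stop("cosinor input must be gap-free")
  if (series_span(series) < tau)
    stop("series must span at least one trial period")
  if (tau <= 2 * series$dt)
    stop("trial period at or below 2*dt makes the design singular")
  t <- series_times(series)
  y <- series$values
  X <- cbind(1, cos(2 * pi * t / tau), sin(2 * pi * t / tau))
  beta <- stats::lm.fit(X, y)$coefficients
  mesor <- beta[[1]]
  amplitude <- sqrt(beta[[2]]^2 + beta[[3]]^2)
  acrophase <- atan2(beta[[3]], beta[[2]]) %% (2 * pi)
  fitted <- X %*% beta
  structure(list(tau = tau, mesor = mesor, amplitude = amplitude,
                 acrophase = acrophase,
                 fit_sse = sum((y - fitted)^2),
                 t_range = range(t)),
            class = "cosinor_model")
}

#' Evaluate a cosinor model at arbitrary times
#' @param object A `cosinor_model`.
#' @param t Hours.
#' @param ... Unused.
#' @return `mesor + amplitude * cos(2*pi*t/tau - acrophase)`.
#' @export
predict.cosinor_model <- function(object, t, ...) {
  object$mesor +
    object$amplitude * cos(2 * pi * t / object$tau - object$acrophase)
}

#' @export
print.cosinor_model <- function(x, ...) {
  cat(sprintf(
    "<cosinor: tau=%.3g hr, mesor=%.4g, amplitude=%.4g, acrophase=%.3g rad>\n",
    x$tau, x$mesor, x$amplitude, x$acrophase))
  invisible(x)
}

# min-max scale to [0,1]; a flat trace maps to 0.5 everywhere
.minmax_unit <- function(x) {
  r <- range(x)
  if (r[2] - r[1] <= 0) return(rep(0.5, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Concordance SSE between a dopamine profile and a cosinor
#'
#' Evaluates the locomotor cosinor at the dialysate sample midpoints,
#' min-max normalizes both the evaluated cosinor and the dopamine profile
#' to `[0, 1]` (so animals with different absolute dopamine and activity
#' scales are comparable on one dimensionless scale), and returns the sum
#' of squared differences. A flat profile cannot be normalized and is
#' rejected as incomparable; a flat cosinor (zero amplitude) maps to the
#' 0.5 midline, under which all permutations of the profile tie.
#'
#' @param model A `cosinor_model`.
#' @param profile A `dialysate_profile` with at least 4 samples.
#' @return Dimensionless SSE (>= 0).
#' @export
concordance_sse <- function(model, profile) {
  if (length(profile$sample_times) < 4L) stop("need at least 4 samples")
  conc <- profile$concentrations
  if (max(conc) - min(conc) <= 0)
    stop("degenerate (flat) profile cannot be normalized; incomparable")
  cz <- .minmax_unit(predict(model, profile$sample_times))
  pz <- .minmax_unit(conc)
  sum((pz - cz)^2)
}

# run `expr` under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# core of the permutation test: profile values already normalized are
# permuted over the fixed (normalized) cosinor samples; only the cross
# term varies across permutations, so SSE_perm = const - 2 * sum(p_perm*c)
.fdr_from_perms <- function(pz, cz, perm_fun, n_perm) {
  obs <- sum((pz - cz)^2)
  crosses <- perm_fun(pz, cz, n_perm)
  sse <- (sum(pz^2) + sum(cz^2)) - 2 * crosses
  tol <- 1e-9 * (1 + obs)
  list(observed_sse = obs,
       fdr_percent = 100 * mean(sse <= obs + tol),
       n = length(sse))
}

#' Permutation false-discovery rate for dopamine-cosinor concordance
#'
#' Randomly permutes the temporal order of the measured dopamine
#' concentrations across the fixed sample times (independent uniform
#' draws of orderings, with replacement — the identity ordering may
#' recur) and reports the percentage of permuted profiles whose
#' normalized SSE against the cosinor is equal to or better (lower) than
#' the observed profile's. Permutation degrades the fit of a genuinely
#' rhythmic profile but leaves a flat or noisy profile's fit
#' distribution unchanged, so a small percentage indicates true
#' concordance. Min-max normalization of the profile is invariant under
#' permutation and affine rescaling, so the result depends only on the
#' ordering of the concentrations.
#'
#' @param model A `cosinor_model`.
#' @param profile A `dialysate_profile`.
#' @param n_perm Number of random permutations (default 100000).
#' @param seed Integer seed; recorded in the result.
#' @return An object of class `concordance_result`: `observed_sse`,
#'   `n_permutations`, `fdr_percent`, `seed`, `exhaustive = FALSE`.
#' @export
permutation_fdr <- function(model, profile, n_perm = 100000, seed = 1) {
  if (n_perm < 1) stop("`n_perm` must be at least 1")
  conc <- profile$concentrations
  if (max(conc) - min(conc) <= 0)
    stop("degenerate (flat) profile cannot be normalized; incomparable")
  pz <- .minmax_unit(conc)
  cz <- .minmax_unit(predict(model, profile$sample_times))
  res <- .with_seed(seed, .fdr_from_perms(pz, cz, function(p, c, m) {
    nn <- length(p)
    P <- vapply(seq_len(m), function(i) p[sample.int(nn)], numeric(nn))
    as.numeric(crossprod(P, c))
  }, n_perm))
  structure(list(observed_sse = res$observed_sse,
                 n_permutations = as.integer(n_perm),
                 fdr_percent = res$fdr_percent,
                 seed = as.integer(seed), exhaustive = FALSE),
            class = "concordance_result")
}

#' Exhaustive-enumeration FDR (small profiles)
#'
#' Enumerates all `n!` orderings of the profile (n <= 8) and reports the
#' exact percentage with SSE equal to or better than observed. Serves as
#' the ground-truth reference for `permutation_fdr`.
#'
#' @param model A `cosinor_model`.
#' @param profile A `dialysate_profile` with at most 8 samples.
#' @return A `concordance_result` with `exhaustive = TRUE` and
#'   `n_permutations = n!`.
#' @export
exhaustive_fdr <- function(model, profile) {
  conc <- profile$concentrations
  nn <- length(conc)
  if (nn > 8L) stop("exhaustive enumeration limited to 8 samples")
  if (max(conc) - min(conc) <= 0)
    stop("degenerate (flat) profile cannot be normalized; incomparable")
  pz <- .minmax_unit(conc)
  cz <- .minmax_unit(predict(model, profile$sample_times))
  perms <- .all_permutations(nn)
  res <- .fdr_from_perms(pz, cz, function(p, c, m) {
    as.numeric(matrix(p[perms], nrow = nrow(perms)) %*% c)
  }, nrow(perms))
  structure(list(observed_sse = res$observed_sse,
                 n_permutations = nrow(perms),
                 fdr_percent = res$fdr_percent,
                 seed = NA_integer_, exhaustive = TRUE),
            class = "concordance_result")
}

# all n! permutations of 1:n as rows of a matrix
.all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .all_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("<concordance: SSE=%.4g, FDR=%.3g%% over %d %s permutations>\n",
              x$observed_sse, x$fdr_percent, x$n_permutations,
              if (x$exhaustive) "exhaustive" else "random"))
  invisible(x)
}

#' Linear regression of ultradian period on dopamine tone
#'
#' Ordinary least squares of the called period on the per-animal mean
#' dopamine concentration (or any tone proxy), with the two-sided test of
#' the slope — the cohort-level summary of the period-dopamine
#' relationship.
#'
#' @param taus Periods, hours (one per animal).
#' @param tones Matched dopamine concentrations or tone values.
#' @return List: `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
period_tone_regression <- function(taus, tones) {
  ok <- is.finite(taus) & is.finite(tones)
  if (sum(ok) < 3L) stop("need at least 3 paired observations")
  fit <- stats::lm(taus[ok] ~ tones[ok])
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2, 4],
       n = sum(ok))
}

#' Rhythm-adjusted mean dopamine of a dialysate profile
#'
#' Mean extracellular dopamine estimated as the mesor of a cosinor fit to
#' the profile at the animal's called period. A raw average over a
#' sampling window shorter than the period is biased by whichever part of
#' the cycle the window caught; the mesor removes that first-order bias,
#' which matters when relating mean dopamine to period across animals.
#' Falls back to the raw mean when `tau` is missing or the window design
#' is near-singular.
#'
#' @param profile A `dialysate_profile`.
#' @param tau Called ultradian period, hours (or `NA`).
#' @return Mean dopamine concentration, nM.
#' @export
profile_mean_da <- function(profile, tau = NA_real_) {
  conc <- profile$concentrations
  if (!is.finite(tau)) return(mean(conc))
  t <- profile$sample_times
  X <- cbind(1, cos(2 * pi * t / tau), sin(2 * pi * t / tau))
  qx <- qr(X)
  if (qx$rank < 3L) return(mean(conc))
  unname(qr.coef(qx, conc)[1])
}
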