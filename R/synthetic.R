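#' Configuration for the dopaminergic ultradian oscillator generator
#'
#' Parameterizes a synthetic animal under the dual-oscillator integration
#' model: an ultradian arousal oscillator whose period is a linear
#' function of dopamine tone, gated (or not) by a circadian process, with
#' the two outputs integrated into a Poisson activity count per bin.
#'
#' The period law is `tau(tone) = tau0 + period_slope * (tone - 1)`: at
#' the defaults (`tau0 = 4`, `period_slope = 4`) a baseline animal
#' (tone 1) runs at 4 hr and a dopamine-transporter-knockout-like animal
#' (tone 3) at 12 hr — three times longer, matching the observed
#' phenotype contrast.
#'
#' @param tau0 Baseline ultradian period at tone 1, hours (default 4).
#' @param tone Dimensionless dopamine tone (baseline 1).
#' @param period_slope Hours of period per unit tone (default 4).
#' @param circadian_gate `"none"` (clockless animal in DD),
#'   `"ld_mask"` (intact animal under LD: activity suppressed in the
#'   light phase) or `"endogenous_24h"` (intact animal in DD: suppressed
#'   in the subjective rest phase).
#' @param gate_depth Fraction of activity permitted in the light/rest
#'   phase, in `[0, 1]` (default 0.1).
#' @param bout_shape Exponent of the rectified-cosine bout waveform
#'   (default 2; larger = narrower bouts).
#' @param mean_rate Expected counts per 0.1-hr bin at a bout peak
#'   (default 50).
#' @param cycle_jitter_sd SD of the per-cycle period, hours (default
#'   0.2) — cycle-to-cycle jitter is carried by the phase, which is what
#'   wavelet ridge SD measures.
#' @param duration Recording length, hours (default 168 = 7 days).
#' @param dt Bin width, hours (default 0.1).
#' @param lights_on Hour of lights-on for the LD gate (default 0: the
#'   recording starts at lights-on).
#' @param photoperiod Hours of light per day (default 12).
#' @param seed Integer seed.
#' @return A list of class `duo_config`.
#' @export
duo_config <- function(tau0 = 4, tone = 1, period_slope = 4,
                       circadian_gate = c("none", "ld_mask",
                                          "endogenous_24h"),
                       gate_depth = 0.1, bout_shape = 2, mean_rate = 50,
                       cycle_jitter_sd = 0.2, duration = 168, dt = 0.1,
                       lights_on = 0, photoperiod = 12, seed = 1) {
  circadian_gate <- match.arg(circadian_gate)
  cfg <- list(tau0 = tau0, tone = tone, period_slope = period_slope,
              circadian_gate = circadian_gate, gate_depth = gate_depth,
              bout_shape = bout_shape, mean_rate = mean_rate,
              cycle_jitter_sd = cycle_jitter_sd, duration = duration,
              dt = dt, lights_on = lights_on, photoperiod = photoperiod,
              seed = as.integer(seed))
  class(cfg) <- "duo_config"
  tau <- duo_period(cfg)
  if (!is.finite(tau) || tau <= 2 * dt)
    stop("tau(tone) must exceed 2*dt")
  if (gate_depth < 0 || gate_depth > 1) stop("`gate_depth` must be in [0,1]")
  if (mean_rate < 0) stop("`mean_rate` must be non-negative")
  if (cycle_jitter_sd < 0) stop("`cycle_jitter_sd` must be non-negative")
  cfg
}

#' Ultradian period implied by a configuration's dopamine tone
#' @param cfg A `duo_config`.
#' @return `tau0 + period_slope * (tone - 1)`, hours.
#' @export
duo_period <- function(cfg) {
  cfg$tau0 + cfg$period_slope * (cfg$tone - 1)
}

# draw consecutive cycle periods covering `span` hours, starting phase
# phase0 (cycles); returns onset times (phase-zero crossings) and periods
.draw_cycles <- function(tau, jitter, span, start, phase0) {
  onsets <- numeric(0); periods <- numeric(0)
  # back up so the first cycle covers `start` at the requested phase
  p1 <- max(tau + if (jitter > 0) stats::rnorm(1, 0, jitter) else 0, 1e-3)
  t <- start - (phase0 %% 1) * p1
  repeat {
    p <- if (length(onsets) == 0) p1 else
      max(tau + if (jitter > 0) stats::rnorm(1, 0, jitter) else 0, 1e-3)
    onsets <- c(onsets, t); periods <- c(periods, p)
    t <- t + p
    if (t >= start + span) break
  }
  list(onsets = onsets, periods = periods)
}

# ultradian phase (in cycles, peak at integer phase) at times tt for one
# cycle train
.phase_in_train <- function(tt, onsets, periods) {
  i <- findInterval(tt, onsets)
  i[i < 1] <- 1L
  (tt - onsets[i]) / periods[i]
}

#' Simulate one animal's activity under the DUO model
#'
#' The expected count in the bin at time `t` (bin midpoint) is
#' `mean_rate * (dt/0.1) * G(t) * max(0, cos(2*pi*phi_u(t)))^bout_shape`,
#' with the ultradian phase `phi_u` advancing through consecutive cycles
#' whose periods are drawn `Normal(tau(tone), cycle_jitter_sd)`; counts
#' are Poisson. For gated configurations the ultradian oscillator is
#' re-anchored at each dark-phase (or subjective-night) onset — light
#' entrains both oscillators in the dual-oscillator model — with the
#' first bout peak placed half a period after onset, producing the
#' evenly spaced night-time bouts seen in intact animals.
#'
#' @param cfg A `duo_config`.
#' @return A list: `record` (an `animal_record`), `truth` (list with the
#'   per-cycle `onsets`, `periods`, realized `tau`, the `phase_at(t)`
#'   function and the config).
#' @export
simulate_activity <- function(cfg) {
  stopifnot(inherits(cfg, "duo_config"))
  .with_seed(cfg$seed, {
    dt <- cfg$dt
    nb <- round(cfg$duration / dt)
    tt <- (seq_len(nb) - 0.5) * dt       # bin midpoints
    tau <- duo_period(cfg)
    gate <- rep(1, nb)
    if (cfg$circadian_gate == "none") {
      tr <- .draw_cycles(tau, cfg$cycle_jitter_sd, cfg$duration, 0, 0)
      trains <- list(tr)
      seg_start <- 0
      phase <- .phase_in_train(tt, tr$onsets, tr$periods)
    } else {
      # rest phase: lights-on .. lights-on+photoperiod (LD), or the
      # subjective day 0..12 (endogenous); active phase follows it
      rest_start <- if (cfg$circadian_gate == "ld_mask") cfg$lights_on else 0
      rest_len <- if (cfg$circadian_gate == "ld_mask") cfg$photoperiod else 12
      tod <- (tt - rest_start) %% 24
      gate[tod < rest_len] <- cfg$gate_depth
      # one cycle train per day, re-anchored at each active-phase onset
      # with the first bout peak half a period in
      day_onsets <- seq(rest_start + rest_len - 24, cfg$duration, by = 24)
      trains <- lapply(day_onsets, function(d0)
        .draw_cycles(tau, cfg$cycle_jitter_sd, 24, d0, -0.5))
      seg <- findInterval(tt, day_onsets)
      seg[seg < 1] <- 1L
      phase <- numeric(nb)
      for (k in seq_along(trains)) {
        in_k <- seg == k
        if (any(in_k))
          phase[in_k] <- .phase_in_train(tt[in_k], trains[[k]]$onsets,
                                         trains[[k]]$periods)
      }
      seg_start <- day_onsets
    }
    lam <- cfg$mean_rate * (dt / 0.1) * gate *
      pmax(0, cos(2 * pi * phase))^cfg$bout_shape
    counts <- stats::rpois(nb, lam)
    act <- uniform_series(counts, dt = dt, t0 = 0, kind = "activity")
    lighting <- switch(cfg$circadian_gate,
      none = lighting_schedule("DD"),
      ld_mask = lighting_schedule("LD", lights_on = cfg$lights_on,
                                  photoperiod = cfg$photoperiod),
      endogenous_24h = lighting_schedule("DD"))
    rec <- animal_record(animal_id = sprintf("sim-seed%d", cfg$seed),
                         genotype_tag = sprintf("tone=%.3g", cfg$tone),
                         activity = act, lighting = lighting)
    truth <- list(config = cfg, tau = tau, trains = trains,
                  seg_start = seg_start,
                  onsets = unlist(lapply(trains, `[[`, "onsets")),
                  periods = unlist(lapply(trains, `[[`, "periods")))
    truth$phase_at <- .make_phase_fun(truth)
    list(record = rec, truth = truth)
  })
}

.make_phase_fun <- function(truth) {
  trains <- truth$trains
  seg_start <- truth$seg_start
  function(t) {
    if (length(trains) == 1L)
      return(.phase_in_train(t, trains[[1]]$onsets, trains[[1]]$periods))
    seg <- findInterval(t, seg_start)
    seg[seg < 1] <- 1L
    out <- numeric(length(t))
    for (k in seq_along(trains)) {
      in_k <- seg == k
      if (any(in_k))
        out[in_k] <- .phase_in_train(t[in_k], trains[[k]]$onsets,
                                     trains[[k]]$periods)
    }
    out
  }
}

#' Configuration for the coupled dialysate dopamine profile
#'
#' @param mean_da Mean extracellular dopamine, nM (default 1.5).
#' @param rel_amplitude Fractional fluctuation amplitude in `[0, 1)`
#'   (default 0.3).
#' @param phase_offset Phase of dopamine relative to the activity bout
#'   peak, radians (default 0: dopamine peaks with the bout).
#' @param noise_sd Additive measurement noise SD, nM (default
#'   `0.1 * mean_da`).
#' @param interval Sampling interval, hours (default 1/3 = 20 min).
#' @param n_samples Number of dialysate samples (default 12, i.e. a 4-hr
#'   session).
#' @return A list of class `da_coupling_config`.
#' @export
da_coupling_config <- function(mean_da = 1.5, rel_amplitude = 0.3,
                               phase_offset = 0, noise_sd = 0.1 * mean_da,
                               interval = 1/3, n_samples = 12) {
  if (mean_da <= 0) stop("`mean_da` must be positive")
  if (rel_amplitude < 0 || rel_amplitude >= 1)
    stop("`rel_amplitude` must be in [0, 1)")
  if (n_samples < 4) stop("need at least 4 samples")
  structure(list(mean_da = mean_da, rel_amplitude = rel_amplitude,
                 phase_offset = phase_offset, noise_sd = noise_sd,
                 interval = interval, n_samples = as.integer(n_samples)),
            class = "da_coupling_config")
}

#' Simulate a dialysate dopamine profile phase-coupled to activity
#'
#' Dopamine at sample midpoint `t` is
#' `mean_da * (1 + rel_amplitude * cos(2*pi*phi_u(t) + phase_offset))`
#' plus Gaussian measurement noise, clipped at zero — extracellular
#' dopamine fluctuating in phase with the activity cycles.
#'
#' @param truth Truth record from [simulate_activity()].
#' @param cfg A `da_coupling_config`.
#' @param start_hr Start of the sampling session, hours (default 0).
#' @param seed Integer seed for the measurement noise (default: the
#'   activity seed + 1).
#' @return A `dialysate_profile`.
#' @export
simulate_da_profile <- function(truth, cfg = da_coupling_config(),
                                start_hr = 0,
                                seed = truth$config$seed + 1L) {
  span <- truth$config$duration
  t_end <- start_hr + cfg$n_samples * cfg$interval
  if (start_hr < 0 || t_end > span)
    stop("sampling window outside the simulated span")
  ts <- start_hr + (seq_len(cfg$n_samples) - 0.5) * cfg$interval
  phi <- truth$phase_at(ts)
  .with_seed(seed, {
    conc <- cfg$mean_da *
      (1 + cfg$rel_amplitude * cos(2 * pi * phi + cfg$phase_offset)) +
      stats::rnorm(cfg$n_samples, 0, cfg$noise_sd)
    dialysate_profile(ts, pmax(conc, 0), interval = cfg$interval)
  })
}

#' Simulate a cohort of animals with tone-dependent periods
#'
#' Draws per-animal dopamine tones uniformly in `tone_range`, simulates
#' each animal's activity under the period-tone law and a dialysate
#' profile with `mean_da = da_per_tone * tone`. The default tone range
#' `c(0.8, 1.8)` emulates the natural inter-animal spread of an
#' untreated clockless cohort (periods roughly 3-7 hr), the setting of
#' the period-vs-dopamine regression.
#'
#' @param n_animals Number of animals (>= 3; default 8).
#' @param tone_range `c(lo, hi)` for the uniform tone draw (default
#'   `c(0.8, 1.8)`).
#' @param base_cfg Template `duo_config`; per-animal tone and seed are
#'   overridden.
#' @param da_per_tone Mean dopamine per unit tone, nM (default 1.5).
#' @param da_cfg Template `da_coupling_config`; per-animal `mean_da` is
#'   overridden and each animal gets a random sampling start phase.
#' @param seed Cohort seed.
#' @return A list of class `duo_cohort`: `animals` (each with `record`,
#'   `truth`, `profile`) and `truth_table` (data frame of `animal_id`,
#'   `tone`, `tau_true`, `mean_da_true`).
#' @export
simulate_cohort <- function(n_animals = 8, tone_range = c(0.8, 1.8),
                            base_cfg = duo_config(), da_per_tone = 1.5,
                            da_cfg = da_coupling_config(), seed = 1) {
  if (n_animals < 3) stop("need at least 3 animals")
  .with_seed(seed, {
    tones <- stats::runif(n_animals, tone_range[1], tone_range[2])
    seeds <- sample.int(2^30, n_animals)
    starts <- stats::runif(n_animals, 0,
                           base_cfg$duration -
                             da_cfg$n_samples * da_cfg$interval)
    animals <- vector("list", n_animals)
    for (i in seq_len(n_animals)) {
      cfg_i <- base_cfg
      cfg_i$tone <- tones[i]
      cfg_i$seed <- seeds[i]
      sim <- simulate_activity(cfg_i)
      da_i <- da_cfg
      da_i$mean_da <- da_per_tone * tones[i]
      da_i$noise_sd <- 0.1 * da_i$mean_da
      prof <- simulate_da_profile(sim$truth, da_i, start_hr = starts[i],
                                  seed = seeds[i] + 1L)
      sim$profile <- prof
      animals[[i]] <- sim
    }
    tt <- data.frame(
      animal_id = vapply(animals, function(a) a$record$animal_id, ""),
      tone = tones,
      tau_true = vapply(animals, function(a) a$truth$tau, 0),
      mean_da_true = da_per_tone * tones)
    structure(list(animals = animals, truth_table = tt, seed = seed),
              class = "duo_cohort")
  })
}

#' Map a drug dose to a dopamine tone multiplier
#'
#' Monotone dose-tone maps summarizing the pharmacology: dopamine
#' reuptake blockers (methamphetamine, amphetamine) raise tone with dose
#' — methamphetamine with the larger gain, reaching tone 3 at 100 mg/l —
#' while the D2 antagonist haloperidol lowers tone toward a positive
#' floor. Dose 0 maps to tone 1 for every drug. These are steady-state
#' maps, not pharmacokinetics.
#'
#' @param drug `"meth"`, `"amphetamine"` or `"haloperidol"`.
#' @param dose Dose, mg/l drinking water (meth, haloperidol) or mg/day
#'   (amphetamine). Must be non-negative.
#' @return Tone multiplier (> 0).
#' @export
dose_to_tone <- function(drug = c("meth", "amphetamine", "haloperidol"),
                         dose) {
  drug <- match.arg(drug)
  if (any(dose < 0)) stop("`dose` must be non-negative")
  switch(drug,
    meth = 1 + dose / 50,
    amphetamine = 1 + dose / 100,
    haloperidol = 0.4 + 0.6 * exp(-dose / 25))
}
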