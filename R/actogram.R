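#' Build an actogram matrix
#'
#' Wraps a series row-wise at the chosen modulo period — 24 hr for the
#' conventional actogram, or the called ultradian period to confirm a
#' rhythm by eye (phase alignment down the rows rules out harmonics and
#' side lobes). The trailing partial cycle is dropped; missing bins
#' become `NA` (rendered blank). In a double plot row `i` shows cycles
#' `i` and `i+1` side by side (left = cycle `i`, right = cycle `i+1`,
#' the standard chronobiology convention).
#'
#' @param series A `uniform_series` spanning at least one modulo cycle.
#' @param modulo Wrap period, hours.
#' @param double_plot Logical (default `TRUE`).
#' @param lighting Optional `lighting_schedule` for a light/dark column
#'   annotation (only meaningful at `modulo = 24`).
#' @return An object of class `actogram`: `rows` (matrix, one row per
#'   cycle; width doubled when double-plotted), `modulo`, `dt`,
#'   `double_plot`, `light_on` (logical per column or `NULL`).
#' @export
build_actogram <- function(series, modulo, double_plot = TRUE,
                           lighting = NULL) {
  dt <- series$dt
  nb <- round(modulo / dt)
  if (abs(modulo / dt - nb) > 1e-6)
    stop("`modulo` must be an integer number of bins")
  n_rows <- floor(length(series$values) / nb)
  if (n_rows < 1) stop("series shorter than one modulo cycle")
  v <- series$values
  v[series$missing_mask] <- NA_real_
  m <- matrix(v[seq_len(n_rows * nb)], nrow = n_rows, ncol = nb,
              byrow = TRUE)
  if (double_plot) {
    nxt <- rbind(m[-1, , drop = FALSE], matrix(NA_real_, 1, nb))
    m <- cbind(m, nxt)
  }
  light_on <- NULL
  if (!is.null(lighting) && lighting$regime == "LD") {
    ph <- ((seq_len(ncol(m)) - 1) * dt + series$t0) %% 24
    light_on <- ph >= lighting$lights_on &
      ph < lighting$lights_on + lighting$photoperiod
  }
  structure(list(rows = m, modulo = modulo, dt = dt,
                 double_plot = double_plot, light_on = light_on),
            class = "actogram")
}

#' @export
print.actogram <- function(x, ...) {
  cat(sprintf("<actogram: %d rows x %d bins, modulo %.3g hr%s>\n",
              nrow(x$rows), ncol(x$rows), x$modulo,
              if (x$double_plot) ", double-plotted" else ""))
  invisible(x)
}

#' Plot an actogram as a tick raster
#'
#' One row per modulo cycle, tick height proportional to the bin value.
#' For temperature series the conventional display maps 34-38 degrees C
#' to the tick-height range (clipped); override with `value_range`.
#'
#' @param x An `actogram`.
#' @param value_range Values mapped to tick heights 0..1; defaults to
#'   `c(34, 38)` for temperature-like data (values all within 30..45),
#'   otherwise `c(0, max)`.
#' @param col Tick color.
#' @param main Plot title.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.actogram <- function(x, value_range = NULL, col = "black",
                          main = "", ...) {
  m <- x$rows
  if (is.null(value_range)) {
    rng <- range(m, na.rm = TRUE)
    value_range <- if (rng[1] >= 30 && rng[2] <= 45) c(34, 38)
                   else c(0, max(rng[2], 1e-12))
  }
  h <- (m - value_range[1]) / diff(value_range)
  h[!is.finite(h)] <- NA
  h <- pmin(pmax(h, 0), 1)
  nr <- nrow(m); nc <- ncol(m)
  graphics::plot(NA, xlim = c(0, nc * x$dt), ylim = c(nr, 0),
                 xlab = sprintf("time (hr, modulo %.3g)", x$modulo),
                 ylab = "cycle", yaxs = "i", main = main, ...)
  if (!is.null(x$light_on) && any(x$light_on)) {
    xs <- (which(x$light_on) - 1) * x$dt
    graphics::rect(xs, nr, xs + x$dt, 0, col = "#FFF5CC", border = NA)
  }
  for (r in seq_len(nr)) {
    ok <- which(!is.na(h[r, ]) & h[r, ] > 0)
    if (length(ok))
      graphics::segments((ok - 1) * x$dt, r, (ok - 1) * x$dt,
                         r - 0.9 * h[r, ok], col = col)
  }
  invisible(x)
}

#' Plot a scalogram heat map with its ridge
#'
#' @param x A `scalogram`.
#' @param ridge Optional `ridge_trace` to overlay.
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.scalogram <- function(x, ridge = NULL, ...) {
  graphics::image(x$times, log2(x$periods), t(x$amp_db),
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "time (hr)", ylab = "period (hr, log2)",
                  yaxt = "n", ...)
  at <- pretty(log2(x$periods))
  graphics::axis(2, at = at, labels = signif(2^at, 3))
  if (!is.null(ridge)) {
    rp <- ridge$ridge_periods
    rp[ridge$in_coi] <- NA
    graphics::lines(ridge$times, log2(rp), col = "black", lwd = 1.5)
  }
  invisible(x)
}

#' Run the full analysis pipeline on one animal
#'
#' Orchestrates window extraction, period estimation, amplitude spectral
#' density, and optionally the wavelet ridge, the dopamine cosinor-FDR
#' stage and actogram construction, from a single configuration list.
#' Stages that lack their inputs are skipped and noted in the report.
#'
#' @param record An `animal_record` (or a `uniform_series`, wrapped
#'   automatically).
#' @param profile Optional `dialysate_profile` for the cosinor-FDR stage.
#' @param config List of options: `window_start`, `window_hr` (analysis
#'   window; default full span), `band` (period search band, default
#'   `c(1, 12)`), `asd_band` (default `c(2, 8)`), `alpha` (0.01),
#'   `cwt` (logical, default `TRUE`), `fdr_window_hr` (20),
#'   `fdr_rebin_hr` (1/3), `n_perm` (10000), `seed` (1),
#'   `actogram` (logical, default `TRUE`).
#' @return A list of class `duo_report` with elements `period`, `asd`,
#'   `ridge`, `fdr`, `actogram`, `skipped`, `params`.
#' @export
run_pipeline <- function(record, profile = NULL, config = list()) {
  if (inherits(record, "uniform_series"))
    record <- animal_record("anon", activity = record)
  stopifnot(inherits(record, "animal_record"))
  cfg <- utils::modifyList(
    list(window_start = 0, window_hr = NULL, band = c(1, 12),
         asd_band = c(2, 8), alpha = 0.01, cwt = TRUE,
         fdr_window_hr = 20, fdr_rebin_hr = 1/3, n_perm = 10000,
         seed = 1, actogram = TRUE),
    config)
  act <- record$activity
  win <- if (is.null(cfg$window_hr)) act else
    extract_window(act, cfg$window_start, cfg$window_hr)
  skipped <- character(0)

  pg <- compute_lomb_scargle(win, band = c(cfg$band[1], 40),
                             alpha = cfg$alpha)
  est <- estimate_period(pg, validate_harmonics = TRUE,
                         span_hr = series_span(win))
  asd <- amplitude_spectral_density(pg, cfg$asd_band)

  ridge <- NULL
  if (isTRUE(cfg$cwt) && series_span(win) >= 2 * cfg$band[2]) {
    scal <- compute_cwt(win, band = cfg$band)
    ridge <- extract_ridge(scal)
  } else if (isTRUE(cfg$cwt)) skipped <- c(skipped, "cwt")

  fdr <- NULL
  if (!is.null(profile)) {
    t_end <- max(profile$sample_times) + profile$interval / 2
    if (t_end + cfg$fdr_window_hr <= series_span(act) + 1e-9) {
      post <- extract_window(act, t_end, cfg$fdr_window_hr)
      # snap the 20-min target to the nearest multiple of the bin width
      # (wheel data at 0.1 hr cannot be rebinned to exactly 1/3 hr)
      k <- max(1, round(cfg$fdr_rebin_hr / act$dt))
      post <- rebin(interpolate_missing(post), k * act$dt)
      pg20 <- compute_lomb_scargle(post, band = c(1, 12),
                                   alpha = cfg$alpha)
      est20 <- estimate_period(pg20, validate_harmonics = FALSE)
      if (est20$significant) {
        cm <- fit_cosinor(post, est20$tau)
        fdr <- permutation_fdr(cm, profile, n_perm = cfg$n_perm,
                               seed = cfg$seed)
        fdr <- c(unclass(fdr), list(tau = est20$tau, mesor = cm$mesor,
                                    amplitude = cm$amplitude,
                                    acrophase = cm$acrophase))
      } else skipped <- c(skipped, "cosinor_fdr (no significant period)")
    } else skipped <- c(skipped, "cosinor_fdr (window beyond recording)")
  } else skipped <- c(skipped, "cosinor_fdr (no dopamine profile)")

  acto <- NULL
  if (isTRUE(cfg$actogram)) {
    modulo <- if (est$significant) est$tau else 24
    modulo <- round(modulo / act$dt) * act$dt
    if (series_span(win) >= modulo)
      acto <- build_actogram(win, modulo)
  }

  structure(list(
    period = list(tau = est$tau, significant = est$significant,
                  peak_power = est$peak_power,
                  harmonic_flags = est$harmonic_flags,
                  threshold = pg$threshold),
    asd = list(band = cfg$asd_band, percent = as.numeric(asd),
               empty_spectrum = isTRUE(attr(asd, "empty_spectrum"))),
    ridge = if (!is.null(ridge))
      list(mean_period = ridge$mean_period, sd_period = ridge$sd_period),
    fdr = fdr,
    actogram = acto,
    skipped = skipped,
    params = cfg),
    class = "duo_report")
}

#' Serialize a pipeline report as JSON
#'
#' Deterministic for a fixed record, profile, config and seed: identical
#' runs produce byte-identical JSON.
#'
#' @param report A `duo_report`.
#' @param path Optional output file.
#' @return The JSON string, invisibly if written to `path`.
#' @export
report_json <- function(report, path = NULL) {
  r <- unclass(report)
  r$actogram <- if (!is.null(r$actogram))
    list(rows = nrow(r$actogram$rows), cols = ncol(r$actogram$rows),
         modulo = r$actogram$modulo)
  js <- jsonlite::toJSON(r, auto_unbox = TRUE, digits = 10, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
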