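#' Uniformly binned behavioral time series
#'
#' Container for evenly binned locomotor-activity counts or core body
#' temperature. Bin timestamps are the left edges of half-open bins
#' `[t, t + dt)`; the time of bin `i` (1-based) is `t0 + (i - 1) * dt`,
#' in decimal hours from recording start. Missing bins are carried as a
#' mask and never imputed.
#'
#' @param values Numeric vector of counts per bin (activity) or degrees
#'   Celsius (temperature).
#' @param dt Bin width in hours (e.g. 0.1 for 6-min bins).
#' @param t0 Time of the first bin's left edge, hours. Default 0.
#' @param missing_mask Logical vector, `TRUE` where the bin is missing.
#'   Defaults to `is.na(values)`.
#' @param kind `"activity"` (non-negative counts) or `"temperature"`.
#' @return An object of class `uniform_series`.
#' @export
uniform_series <- function(values, dt, t0 = 0, missing_mask = NULL,
                           kind = c("activity", "temperature")) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (is.null(missing_mask)) missing_mask <- is.na(values)
  missing_mask <- as.logical(missing_mask)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a single positive number (hours)")
  if (length(values) != length(missing_mask))
    stop("`values` and `missing_mask` must have the same length")
  if (kind == "activity" && any(values[!missing_mask] < 0, na.rm = TRUE))
    stop("activity counts must be non-negative where not missing")
  if (anyNA(values[!missing_mask]))
    stop("non-missing bins must hold finite values")
  structure(
    list(t0 = as.numeric(t0), dt = dt, values = values,
         missing_mask = missing_mask, kind = kind),
    class = "uniform_series"
  )
}

#' @export
print.uniform_series <- function(x, ...) {
  cat(sprintf("<uniform_series: %s, %d bins of %.4g hr (%.1f hr), %d missing>\n",
              x$kind, length(x$values), x$dt, series_span(x),
              sum(x$missing_mask)))
  invisible(x)
}

#' @export
length.uniform_series <- function(x) length(x$values)

#' Bin left-edge timestamps of a series, in hours
#' @param series A `uniform_series`.
#' @return Numeric vector `t0 + (0:(n-1)) * dt`.
#' @export
series_times <- function(series) {
  series$t0 + (seq_along(series$values) - 1) * series$dt
}

#' Recording span of a series, in hours
#' @param series A `uniform_series`.
#' @return `n * dt`.
#' @export
series_span <- function(series) length(series$values) * series$dt

#' Lighting schedule descriptor
#'
#' @param regime `"LD"` (light:dark cycle), `"DD"` (constant darkness) or
#'   `"dim_red"` (constant dim red light, used during microdialysis).
#' @param lights_on Hour offset of lights-on within the 24-hr day.
#' @param photoperiod Hours of light per 24-hr cycle. Ignored for
#'   `"DD"`/`"dim_red"`.
#' @return An object of class `lighting_schedule`.
#' @export
lighting_schedule <- function(regime = c("LD", "DD", "dim_red"),
                              lights_on = 0, photoperiod = 12) {
  regime <- match.arg(regime)
  if (lights_on < 0 || lights_on >= 24) stop("`lights_on` must be in [0, 24)")
  if (photoperiod < 0 || photoperiod > 24)
    stop("`photoperiod` must be in [0, 24]")
  structure(list(regime = regime, lights_on = lights_on,
                 photoperiod = photoperiod),
            class = "lighting_schedule")
}

#' Dialysate dopamine concentration profile
#'
#' A short, evenly sampled extracellular dopamine trace, one concentration
#' per dialysate sample. `sample_times` are sample-interval midpoints in
#' hours, which aligns each concentration with the cosinor evaluation time
#' at the middle of its collection interval.
#'
#' @param sample_times Strictly increasing, evenly spaced hour vector.
#' @param concentrations Non-negative concentrations, nM.
#' @param interval Sampling interval in hours (default 1/3, i.e. 20 min).
#' @return An object of class `dialysate_profile`.
#' @export
dialysate_profile <- function(sample_times, concentrations, interval = 1/3) {
  sample_times <- as.numeric(sample_times)
  concentrations <- as.numeric(concentrations)
  n <- length(sample_times)
  if (n < 4L) stop("a dialysate profile needs at least 4 samples")
  if (length(concentrations) != n)
    stop("`sample_times` and `concentrations` must have the same length")
  d <- diff(sample_times)
  if (any(d <= 0)) stop("`sample_times` must be strictly increasing")
  if (max(abs(d - d[1])) > 1e-9)
    stop("`sample_times` must be evenly spaced (tolerance 1e-9 hr)")
  if (any(concentrations < 0)) stop("concentrations must be non-negative")
  structure(list(sample_times = sample_times,
                 concentrations = concentrations,
                 interval = interval),
            class = "dialysate_profile")
}

#' Per-animal record bundling activity, temperature and lighting
#'
#' @param animal_id Identifier string.
#' @param genotype_tag Free-text genotype/treatment tag.
#' @param activity `uniform_series` of kind `"activity"`.
#' @param temperature Optional `uniform_series` of kind `"temperature"`.
#' @param lighting A `lighting_schedule`.
#' @param episodes Optional list of treatment episodes, each a list with
#'   `start`, `end` (hours within the recording span), `drug`, `dose`.
#'   Episodes must not overlap.
#' @return An object of class `animal_record`.
#' @export
animal_record <- function(animal_id, genotype_tag = "", activity,
                          temperature = NULL,
                          lighting = lighting_schedule("DD"),
                          episodes = list()) {
  stopifnot(inherits(activity, "uniform_series"))
  if (!is.null(temperature)) stopifnot(inherits(temperature, "uniform_series"))
  stopifnot(inherits(lighting, "lighting_schedule"))
  span <- series_span(activity)
  if (length(episodes)) {
    ivals <- t(vapply(episodes, function(e) c(e$start, e$end), numeric(2)))
    if (any(ivals[, 1] >= ivals[, 2]))
      stop("episode start must precede its end")
    if (any(ivals[, 1] < 0) || any(ivals[, 2] > span + 1e-9))
      stop("episodes must lie within the recording span")
    o <- order(ivals[, 1])
    if (nrow(ivals) > 1 && any(ivals[o, 1][-1] < ivals[o, 2][-nrow(ivals)]))
      stop("episodes must not overlap")
  }
  structure(list(animal_id = animal_id, genotype_tag = genotype_tag,
                 activity = activity, temperature = temperature,
                 lighting = lighting, episodes = episodes),
            class = "animal_record")
}

#' Read a binned series from delimited text
#'
#' Expects a header row with columns `time_hr` and `value` (and optionally
#' `missing`), UTF-8, "." decimal. The bin width is inferred from the
#' smallest time increment; rows absent from the file become masked
#' (missing) bins on the reconstructed uniform grid.
#'
#' @param path File path.
#' @param kind Series kind, `"activity"` or `"temperature"`.
#' @param time_col,value_col Column names (defaults `time_hr`, `value`).
#' @param sep Field separator (default `","`).
#' @return A `uniform_series`.
#' @export
load_series <- function(path, kind = c("activity", "temperature"),
                        time_col = "time_hr", value_col = "value",
                        sep = ",") {
  kind <- match.arg(kind)
  d <- tryCatch(utils::read.table(path, header = TRUE, sep = sep,
                                  stringsAsFactors = FALSE),
                error = function(e) stop("unparseable file: ",
                                         conditionMessage(e)))
  if (!all(c(time_col, value_col) %in% names(d)))
    stop(sprintf("file must contain columns '%s' and '%s'",
                 time_col, value_col))
  tt <- as.numeric(d[[time_col]])
  vv <- as.numeric(d[[value_col]])
  if (anyNA(tt)) stop("unparseable time column")
  dtt <- diff(tt)
  if (any(dtt <= 0)) stop("time column must be strictly increasing")
  dt <- min(dtt)
  k <- dtt / dt
  if (max(abs(k - round(k))) > 1e-6)
    stop("irregular bin spacing beyond tolerance 1e-6*dt")
  idx <- c(0, cumsum(round(k))) + 1L      # position on the full grid
  n <- idx[length(idx)]
  values <- rep(NA_real_, n)
  values[idx] <- vv
  mask <- rep(TRUE, n)
  mask[idx] <- FALSE
  if ("missing" %in% names(d)) {
    mask[idx] <- mask[idx] | as.logical(d$missing)
    values[mask] <- NA_real_
  }
  uniform_series(values, dt = dt, t0 = tt[1], missing_mask = mask, kind = kind)
}

#' Write a series as CSV (`time_hr,value,missing`)
#'
#' Missing bins are written with an empty value and `missing = 1` so that
#' a write/read round trip reproduces values, mask and bin width exactly.
#'
#' @param series A `uniform_series`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  d <- data.frame(time_hr = series_times(series),
                  value = ifelse(series$missing_mask, NA, series$values),
                  missing = as.integer(series$missing_mask))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a ClockLab-style AWD activity file
#'
#' One count per line following a 7-line header block (animal id, start
#' date, start time, bin length in minutes, age, sex, genotype). Counts of
#' `-1` or blank lines inside the data block are treated as missing bins.
#'
#' @param path File path.
#' @return A `uniform_series` of kind `"activity"` with `t0 = 0`.
#' @export
read_awd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 8L) stop("unparseable AWD file: too short")
  bin_min <- suppressWarnings(as.numeric(trimws(lines[4])))
  if (!is.finite(bin_min) || bin_min <= 0)
    stop("unparseable AWD file: bad bin length in header line 4")
  raw <- trimws(lines[-(1:7)])
  while (length(raw) && !nzchar(raw[length(raw)])) raw <- raw[-length(raw)]
  vals <- suppressWarnings(as.numeric(raw))
  miss <- !nzchar(raw) | (!is.na(vals) & vals < 0) | is.na(vals)
  vals[miss] <- NA_real_
  uniform_series(vals, dt = bin_min / 60, t0 = 0, missing_mask = miss,
                 kind = "activity")
}

#' Rebin a series to a coarser bin width
#'
#' Counts are summed within each new bin; temperature is averaged. A new
#' bin is missing iff all its constituent bins are missing, so the total
#' non-missing count is conserved. The trailing partial group, if any, is
#' dropped.
#'
#' @param series A `uniform_series`.
#' @param new_dt New bin width in hours; must be an integer multiple of
#'   `series$dt`.
#' @return A `uniform_series` at the new bin width.
#' @export
rebin <- function(series, new_dt) {
  r <- new_dt / series$dt
  if (abs(r - round(r)) > 1e-9 || round(r) < 1)
    stop("`new_dt` must be an integer multiple of the current bin width")
  r <- as.integer(round(r))
  if (r == 1L) return(series)
  n_new <- length(series$values) %/% r
  if (n_new < 1L) stop("series shorter than one new bin")
  idx <- rep(seq_len(n_new), each = r)
  v <- series$values[seq_len(n_new * r)]
  m <- series$missing_mask[seq_len(n_new * r)]
  v[m] <- NA_real_
  agg <- if (series$kind == "activity") {
    tapply(v, idx, function(x) sum(x, na.rm = TRUE))
  } else {
    tapply(v, idx, function(x) mean(x, na.rm = TRUE))
  }
  all_miss <- tapply(m, idx, all)
  vals <- as.numeric(agg)
  vals[all_miss] <- NA_real_
  uniform_series(vals, dt = new_dt, t0 = series$t0,
                 missing_mask = as.logical(all_miss), kind = series$kind)
}

#' Extract a time window from a series
#'
#' @param series A `uniform_series`.
#' @param start Window start, hours (same clock as `series$t0`).
#' @param duration Window length, hours.
#' @return The sub-series with `t0` updated; its length is
#'   `round(duration/dt)` bins.
#' @export
extract_window <- function(series, start, duration) {
  dt <- series$dt
  i0 <- round((start - series$t0) / dt)
  n <- round(duration / dt)
  if (abs((start - series$t0) / dt - i0) > 1e-6)
    stop("`start` must align with the bin grid")
  if (i0 < 0 || n < 1 || i0 + n > length(series$values))
    stop("window outside the recording span")
  sel <- (i0 + 1):(i0 + n)
  uniform_series(series$values[sel], dt = dt, t0 = series$t0 + i0 * dt,
                 missing_mask = series$missing_mask[sel], kind = series$kind)
}

#' Linearly interpolate missing bins
#'
#' Used by stages that need gap-free input (filters, wavelet transform).
#' Interior gaps are linearly interpolated between the flanking non-missing
#' bins; leading/trailing gaps take the nearest non-missing value.
#'
#' @param series A `uniform_series`.
#' @return A gap-free `uniform_series`; the number of interpolated bins is
#'   attached as attribute `"n_interpolated"`.
#' @export
interpolate_missing <- function(series) {
  m <- series$missing_mask
  if (!any(m)) return(series)
  if (all(m)) stop("cannot interpolate a fully missing series")
  t <- series_times(series)
  v <- series$values
  v[m] <- stats::approx(t[!m], v[!m], xout = t[m], rule = 2)$y
  out <- uniform_series(v, dt = series$dt, t0 = series$t0,
                        missing_mask = rep(FALSE, length(v)),
                        kind = series$kind)
  attr(out, "n_interpolated") <- sum(m)
  out
}
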