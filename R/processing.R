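## Measurement-to-xylem-water pipeline for cavity ring-down vapor isotope
## time series: cycle averaging, QC, RH reconstruction, calibration against
## headspace standards, vapor-to-liquid conversion, breakthrough timing.

#' Read a raw measurement CSV
#'
#' Expected columns: `timestamp` (ISO 8601, UTC), `channel`, `h2o_ppm`,
#' `d18o_raw`, `d2h_raw`, `t_stem_c` and optionally `pressure_pa`
#' (101325 Pa assumed when absent).
#'
#' @param path CSV file path.
#' @return data.frame with `timestamp` parsed to POSIXct (UTC).
#' @export
read_raw_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "channel", "h2o_ppm", "d18o_raw", "d2h_raw", "t_stem_c")
  missing <- setdiff(need, names(raw))
  if (length(missing)) stop("raw CSV missing columns: ", paste(missing, collapse = ", "))
  raw$timestamp <- as.POSIXct(raw$timestamp, tz = "UTC",
                              tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  if (anyNA(raw$timestamp)) stop("unparseable timestamps in raw CSV (expect ISO 8601 UTC)")
  if (is.null(raw$pressure_pa)) raw$pressure_pa <- .P0
  raw
}

#' Split a per-sample series into measurement cycles
#'
#' Cycles are separated by gaps in the sampling (the flush period between
#' measurements): within each channel, a new cycle starts wherever the time
#' since the previous sample exceeds `gap_s`.
#'
#' @param raw Per-sample data.frame with `timestamp` and `channel`.
#' @param gap_s Minimum gap (seconds) separating cycles; default 120.
#' @return `raw`, time-ordered within channel, with a `cycle_id` column
#'   (`channel#index`).
#' @export
split_cycles <- function(raw, gap_s = 120) {
  parts <- split(raw, raw$channel)
  out <- lapply(parts, function(d) {
    d <- d[order(d$timestamp), , drop = FALSE]
    gaps <- c(Inf, diff(as.numeric(d$timestamp)))
    idx <- cumsum(gaps > gap_s)
    d$cycle_id <- paste0(d$channel, "#", idx)
    d
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Average one measurement cycle over its trailing window
#'
#' Values stabilize only toward the end of a measurement cycle, so means and
#' standard deviations are computed over the trailing `window_s` seconds of
#' wall-clock time only (default 3 min of a 15 min cycle).
#'
#' @param cycle Per-sample data.frame of a single cycle (columns as in
#'   [read_raw_csv()]).
#' @param window_s Trailing window length (s), default 180.
#' @param min_samples Minimum samples required in the window; fewer sets the
#'   `flag_short_cycle` flag (default 3).
#' @return One-row data.frame: cycle metadata, window means/SDs of
#'   `h2o_ppm`, `d18o_raw`, `d2h_raw`, mean stem temperature and pressure,
#'   and `flag_short_cycle`.
#' @export
average_cycle <- function(cycle, window_s = 180, min_samples = 3L) {
  stopifnot(nrow(cycle) >= 1L)
  cycle <- cycle[order(cycle$timestamp), , drop = FALSE]
  t_end <- max(cycle$timestamp)
  dur <- as.numeric(t_end) - as.numeric(min(cycle$timestamp))
  if (window_s > dur + sqrt(.Machine$double.eps))
    window_s <- dur  # window capped at the cycle itself
  win <- cycle[as.numeric(t_end) - as.numeric(cycle$timestamp) <= window_s, , drop = FALSE]
  short <- nrow(win) < min_samples
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  data.frame(
    channel = cycle$channel[1L],
    cycle_id = if (!is.null(cycle$cycle_id)) cycle$cycle_id[1L] else NA_character_,
    cycle_start = min(cycle$timestamp),
    cycle_end = t_end,
    n_samples = nrow(cycle),
    n_window = nrow(win),
    h2o_ppm_mean = mean(win$h2o_ppm),
    h2o_ppm_sd = sd0(win$h2o_ppm),
    d18o_raw_mean = mean(win$d18o_raw),
    d18o_raw_sd = sd0(win$d18o_raw),
    d2h_raw_mean = mean(win$d2h_raw),
    d2h_raw_sd = sd0(win$d2h_raw),
    t_stem_c_mean = mean(win$t_stem_c),
    pressure_pa = mean(if (is.null(win$pressure_pa)) .P0 else win$pressure_pa),
    flag_short_cycle = short
  )
}

#' Average every cycle of a campaign
#'
#' @param raw Per-sample data.frame; passed through [split_cycles()] first
#'   if it has no `cycle_id` column.
#' @param window_s,min_samples,gap_s See [average_cycle()] and
#'   [split_cycles()].
#' @return data.frame of per-cycle records, time-ordered within channel.
#' @export
average_cycles <- function(raw, window_s = 180, min_samples = 3L, gap_s = 120) {
  if (is.null(raw$cycle_id)) raw <- split_cycles(raw, gap_s = gap_s)
  recs <- lapply(split(raw, raw$cycle_id),
                 average_cycle, window_s = window_s, min_samples = min_samples)
  recs <- do.call(rbind, recs)
  recs <- recs[order(recs$channel, recs$cycle_start), , drop = FALSE]
  rownames(recs) <- NULL
  recs
}

#' Relative humidity in the borehole
#'
#' Compares the measured water-vapor mole fraction to the saturation mole
#' fraction at stem temperature: `h = w / w_sat(T_stem, p)`. Values near 1
#' indicate the borehole air approached saturation (a prerequisite for
#' isotopic equilibration); values above ~1 suggest condensation.
#'
#' @param w Vapor mole fraction (dimensionless; divide ppm by 1e6).
#' @param temperature_K Stem temperature (K); vectorized.
#' @param pressure_Pa Total pressure (Pa).
#' @return Relative humidity (fraction). A warning is raised when any value
#'   exceeds 1.05 (condensation suspect).
#' @export
borehole_rh <- function(w, temperature_K, pressure_Pa = .P0) {
  h <- w / saturation_mole_fraction(temperature_K, pressure_Pa)
  if (any(h > 1.05)) warning("relative humidity above 1.05: condensation suspected")
  h
}

#' Quality-control flags for processed cycles
#'
#' Applies the exclusion rules used on borehole measurements: cycles whose
#' raw-delta standard deviation over the averaging window exceeds 0.5 per
#' mil (delta-18O) or 1.5 per mil (delta-2H), or whose borehole relative
#' humidity is below 0.8, are flagged. Boundaries are inclusive-pass
#' (SD equal to the limit passes; h equal to 0.8 passes). Flagged records
#' are retained, never dropped.
#'
#' @param records Per-cycle data.frame carrying `d18o_raw_sd`, `d2h_raw_sd`
#'   and `rh` columns (see [average_cycles()] and [borehole_rh()]).
#' @param sd_limit_o18,sd_limit_h2 SD exclusion limits (per mil).
#' @param rh_min Minimum acceptable relative humidity (fraction).
#' @return `records` with logical columns `flag_sd_o18`, `flag_sd_h2`,
#'   `flag_low_rh` and `qc_pass` (no flag set, including
#'   `flag_short_cycle` when present).
#' @export
qc_filter <- function(records, sd_limit_o18 = 0.5, sd_limit_h2 = 1.5, rh_min = 0.8) {
  stopifnot(all(c("d18o_raw_sd", "d2h_raw_sd", "rh") %in% names(records)))
  records$flag_sd_o18 <- records$d18o_raw_sd > sd_limit_o18
  records$flag_sd_h2 <- records$d2h_raw_sd > sd_limit_h2
  records$flag_low_rh <- records$rh < rh_min
  short <- if (!is.null(records$flag_short_cycle)) records$flag_short_cycle else FALSE
  records$qc_pass <- !(records$flag_sd_o18 | records$flag_sd_h2 |
                         records$flag_low_rh | short)
  records
}

#' Summarize QC exclusions
#'
#' @param records Output of [qc_filter()].
#' @return List with total cycle count, excluded count and percentage, and
#'   per-flag counts. Counts always satisfy excluded + clean = total.
#' @export
qc_summary <- function(records) {
  n <- nrow(records)
  excl <- sum(!records$qc_pass)
  list(
    n_cycles = n,
    n_excluded = excl,
    n_clean = n - excl,
    pct_excluded = if (n > 0) 100 * excl / n else NA_real_,
    n_flag_sd_o18 = sum(records$flag_sd_o18),
    n_flag_sd_h2 = sum(records$flag_sd_h2),
    n_flag_low_rh = sum(records$flag_low_rh),
    n_flag_short_cycle = if (!is.null(records$flag_short_cycle)) sum(records$flag_short_cycle) else 0L
  )
}

#' Fit a calibration against headspace vapor standards
#'
#' Each standard is a bag of liquid water of known composition whose
#' headspace vapor is measured like a borehole. The target vapor value of a
#' standard is its known liquid delta converted to vapor via equilibrium
#' fractionation at the recorded headspace temperature; the calibration is
#' the per-species ordinary-least-squares line mapping measured to target
#' vapor delta (with exactly two standards this is exact interpolation).
#'
#' @param standards data.frame with columns `name`, `d18o_liquid`,
#'   `d2h_liquid`, `t_headspace_c`, `d18o_meas`, `d2h_meas`.
#' @return A `boreq_calibration` object: list of per-species
#'   `slope`/`intercept` plus the standards with their vapor targets.
#' @export
fit_calibration <- function(standards) {
  need <- c("d18o_liquid", "d2h_liquid", "t_headspace_c", "d18o_meas", "d2h_meas")
  missing <- setdiff(need, names(standards))
  if (length(missing)) stop("standards missing columns: ", paste(missing, collapse = ", "))
  if (nrow(standards) < 2L) stop("at least 2 standards are required to fit a calibration")
  T_K <- standards$t_headspace_c + .T0
  coefs <- list()
  for (sp in BOREQ_SPECIES) {
    liq <- if (sp == "O18") standards$d18o_liquid else standards$d2h_liquid
    meas <- if (sp == "O18") standards$d18o_meas else standards$d2h_meas
    target <- liquid_to_vapor_delta(liq, sp, T_K)
    fit <- stats::lm(target ~ meas)
    coefs[[sp]] <- c(intercept = unname(stats::coef(fit)[1L]),
                     slope = unname(stats::coef(fit)[2L]))
    standards[[paste0(if (sp == "O18") "d18o" else "d2h", "_target_vapor")]] <- target
  }
  structure(list(coefficients = coefs, standards = standards),
            class = "boreq_calibration")
}

#' Apply a calibration to raw vapor deltas
#'
#' @param delta_raw Raw per-mil value(s) from the instrument.
#' @param calibration A [fit_calibration()] object.
#' @param species `"O18"` or `"H2"`.
#' @param warn_extrapolation Warn when values fall outside the measured
#'   range spanned by the standards (default TRUE).
#' @return Calibrated per-mil vapor delta(s): `slope * raw + intercept`.
#' @export
calibrate_delta <- function(delta_raw, calibration, species, warn_extrapolation = TRUE) {
  stopifnot(inherits(calibration, "boreq_calibration"))
  species <- .check_species(species)
  cf <- calibration$coefficients[[species]]
  if (warn_extrapolation) {
    meas <- if (species == "O18") calibration$standards$d18o_meas else calibration$standards$d2h_meas
    if (any(delta_raw < min(meas) | delta_raw > max(meas), na.rm = TRUE))
      warning(sprintf("%s values outside the range spanned by the standards: extrapolating", species))
  }
  cf[["slope"]] * delta_raw + cf[["intercept"]]
}

#' Midpoint timing of a tracer breakthrough curve
#'
#' Estimates the mean arrival time of a tracer front as the time the series
#' first crosses the midpoint between its initial and final plateaus. The
#' plateaus are the means over two user-specified steady-state windows; the
#' crossing time is linearly interpolated between the bracketing samples.
#'
#' @param time Time stamps (numeric or POSIXct), strictly increasing.
#' @param value Measured series (e.g. per-cycle delta values).
#' @param pre_window,post_window Length-2 vectors `c(start, end)` (same
#'   units as `time`) delimiting the initial and final plateaus; each must
#'   contain at least 3 points. A warning is issued when the plateau
#'   difference does not exceed the combined plateau noise.
#' @return A `boreq_breakthrough` list: `initial`, `final`, `midpoint`
#'   (values), `crossing_time` (same class as `time`), `direction`
#'   (+1 rising / -1 falling), plateau SDs and the windows used.
#' @export
breakthrough_midpoint <- function(time, value, pre_window, post_window) {
  stopifnot(length(time) == length(value), length(pre_window) == 2L,
            length(post_window) == 2L)
  tn <- as.numeric(time)
  if (is.unsorted(tn, strictly = TRUE)) stop("time must be strictly increasing")
  pre <- value[tn >= as.numeric(pre_window[1L]) & tn <= as.numeric(pre_window[2L])]
  post <- value[tn >= as.numeric(post_window[1L]) & tn <= as.numeric(post_window[2L])]
  if (length(pre) < 3L || length(post) < 3L)
    stop("each plateau window must contain at least 3 points")
  m1 <- mean(pre); m2 <- mean(post)
  s1 <- stats::sd(pre); s2 <- stats::sd(post)
  if (abs(m2 - m1) <= s1 + s2)
    warning("plateau difference does not exceed combined plateau noise; midpoint timing is unreliable")
  mid <- (m1 + m2) / 2
  dir <- sign(m2 - m1)
  # first crossing after the pre-plateau window ends
  from <- which(tn > as.numeric(pre_window[2L]))
  start_i <- if (length(from)) max(1L, min(from) - 1L) else 1L
  cross_t <- NA_real_
  for (i in seq(start_i, length(value) - 1L)) {
    v0 <- value[i]; v1 <- value[i + 1L]
    if (is.na(v0) || is.na(v1)) next
    if (dir * (v0 - mid) <= 0 && dir * (v1 - mid) >= 0) {
      cross_t <- if (v1 == v0) tn[i] else tn[i] + (mid - v0) / (v1 - v0) * (tn[i + 1L] - tn[i])
      break
    }
  }
  if (is.na(cross_t)) stop("series never crosses the plateau midpoint within the record")
  crossing <- if (inherits(time, "POSIXct")) as.POSIXct(cross_t, origin = "1970-01-01", tz = "UTC") else cross_t
  structure(list(initial = m1, final = m2, midpoint = mid,
                 crossing_time = crossing, direction = dir,
                 initial_sd = s1, final_sd = s2,
                 pre_window = pre_window, post_window = post_window),
            class = "boreq_breakthrough")
}

#' Sap velocity from the tracer lag between two boreholes
#'
#' `velocity = distance / (t_upper - t_lower)`, reported in cm/h.
#'
#' @param distance_m Vertical separation of the two boreholes (m).
#' @param t_lower_h,t_upper_h Arrival times at the lower and upper borehole,
#'   in hours (numeric) or as POSIXct.
#' @return Velocity (cm/h).
#' @examples
#' velocity_from_lag(0.50, 70, 124)  # about 0.93 cm/h
#' @export
velocity_from_lag <- function(distance_m, t_lower_h, t_upper_h) {
  if (distance_m <= 0) stop("distance must be positive")
  lag_h <- if (inherits(t_lower_h, "POSIXct")) {
    as.numeric(difftime(t_upper_h, t_lower_h, units = "hours"))
  } else {
    t_upper_h - t_lower_h
  }
  if (lag_h <= 0) stop("t_upper must be later than t_lower")
  100 * distance_m / lag_h
}

#' Predicted tracer arrival time at a borehole
#'
#' `arrival = distance / velocity`, in hours.
#'
#' @param distance_m Transport distance (m).
#' @param velocity_cm_h Sap velocity (cm/h).
#' @return Duration (h).
#' @examples
#' predicted_arrival(0.40, 100 / 12)  # 4.8 h for 1 m per 12-h day
#' @export
predicted_arrival <- function(distance_m, velocity_cm_h) {
  if (distance_m <= 0 || velocity_cm_h <= 0) stop("distance and velocity must be positive")
  100 * distance_m / velocity_cm_h
}

#' Run the full measurement-processing pipeline
#'
#' Chains cycle splitting, trailing-window averaging, borehole RH
#' reconstruction, calibration against standards, vapor-to-liquid
#' conversion at stem temperature, and QC flagging.
#'
#' @param raw Per-sample data.frame (see [read_raw_csv()]) or a path to a
#'   raw CSV.
#' @param standards Standards data.frame (see [fit_calibration()]), a path
#'   to a standards CSV, or a ready `boreq_calibration` object.
#' @param window_s,min_samples,gap_s Averaging parameters.
#' @param sd_limit_o18,sd_limit_h2,rh_min QC thresholds.
#' @return A `boreq_processed` list: `records` (per-cycle data.frame with
#'   calibrated vapor deltas `d18o_vapor`/`d2h_vapor`, liquid-equivalent
#'   `d18o_liquid`/`d2h_liquid`, `rh` and all QC flags), `calibration`, and
#'   `report` (cycle counts, exclusion percentages, calibration
#'   coefficients).
#' @export
process_campaign <- function(raw, standards, window_s = 180, min_samples = 3L,
                             gap_s = 120, sd_limit_o18 = 0.5, sd_limit_h2 = 1.5,
                             rh_min = 0.8) {
  if (is.character(raw)) raw <- read_raw_csv(raw)
  calibration <- if (inherits(standards, "boreq_calibration")) {
    standards
  } else {
    if (is.character(standards)) standards <- utils::read.csv(standards, stringsAsFactors = FALSE)
    fit_calibration(standards)
  }
  recs <- average_cycles(raw, window_s = window_s, min_samples = min_samples, gap_s = gap_s)
  recs$rh <- borehole_rh(recs$h2o_ppm_mean * 1e-6, recs$t_stem_c_mean + .T0, recs$pressure_pa)
  recs$d18o_vapor <- calibrate_delta(recs$d18o_raw_mean, calibration, "O18", warn_extrapolation = FALSE)
  recs$d2h_vapor <- calibrate_delta(recs$d2h_raw_mean, calibration, "H2", warn_extrapolation = FALSE)
  recs$d18o_liquid <- vapor_to_liquid_delta(recs$d18o_vapor, "O18", recs$t_stem_c_mean + .T0)
  recs$d2h_liquid <- vapor_to_liquid_delta(recs$d2h_vapor, "H2", recs$t_stem_c_mean + .T0)
  recs <- qc_filter(recs, sd_limit_o18 = sd_limit_o18, sd_limit_h2 = sd_limit_h2, rh_min = rh_min)
  summ <- qc_summary(recs)
  structure(list(
    records = recs,
    calibration = calibration,
    report = list(qc = summ,
                  calibration = calibration$coefficients,
                  thresholds = list(sd_limit_o18 = sd_limit_o18,
                                    sd_limit_h2 = sd_limit_h2, rh_min = rh_min),
                  window_s = window_s)
  ), class = "boreq_processed")
}
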