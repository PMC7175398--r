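## Seeded generator of synthetic measurement campaigns and headspace
## standards with the statistical structure the processing pipeline assumes:
## plateau-transition-plateau tracer breakthrough in the liquid xylem water,
## near-saturated borehole vapor, diurnal stem temperature, Gaussian
## instrument noise, and occasional low-RH or SD-burst artifact cycles.

## The paper-style four-standard scheme (light, medium, heavy, label).
.DEFAULT_STANDARDS <- data.frame(
  name = c("light", "medium", "heavy", "label"),
  d18o_liquid = c(-14.9, -9.4, 3.4, -9.2),
  d2h_liquid = c(-110.8, -66.3, 3.8, 367.7),
  stringsAsFactors = FALSE
)

## Run `expr` under `seed` and restore the caller's RNG state afterwards.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Configuration of a synthetic measurement campaign
#'
#' Defines the ground truth of a simulated borehole monitoring campaign:
#' the liquid xylem water follows a plateau-transition-plateau tracer
#' breakthrough, the borehole vapor sits near saturation at a diurnally
#' varying stem temperature, and the instrument adds Gaussian noise plus
#' occasional artifact cycles (sub-saturated flushing or noise bursts).
#'
#' @param duration_h Campaign length (h), default 240 (10 days).
#' @param sampling_interval_h Hours between cycle starts, default 3.
#' @param cycle_length_s Measurement length per cycle (s), default 900
#'   (15 min; the 5 min flush is not emitted).
#' @param sample_period_s Instrument sample period (s), default 5.
#' @param liquid_pre,liquid_post Named per-mil vectors of liquid xylem
#'   composition before/after the label; defaults are a natural-abundance
#'   source and a strong 2H label.
#' @param switch_time_h Time of the source-water switch (h from start).
#' @param transition_tau_h Time constant of the breakthrough (h).
#' @param transition_shape `"exponential"` (relaxation toward the post
#'   plateau; midpoint at `switch + tau*log(2)`) or `"logistic"`
#'   (midpoint at `switch`).
#' @param t_stem_mean_c,t_stem_amplitude_c,t_stem_peak_hour Diurnal stem
#'   temperature: mean (deg C), half-amplitude (deg C) and hour of the
#'   daily maximum.
#' @param rh_true True borehole relative humidity (default 0.98).
#' @param pressure_pa Total pressure (Pa).
#' @param noise_sd Named per-sample Gaussian noise SDs (per mil), default
#'   `c(O18 = 0.25, H2 = 0.75)`: half the QC exclusion limits, so clean
#'   cycles essentially never trip the SD filter (field campaigns exclude
#'   only a few percent of cycles).
#' @param h2o_noise_ppm Gaussian noise SD on the water mole fraction (ppm).
#' @param p_low_rh Probability that a cycle is a low-RH artifact (vapor
#'   multiplied into h below 0.8).
#' @param p_sd_burst Probability that a cycle is an SD-burst artifact
#'   (delta noise inflated 3x, beyond both QC limits).
#' @param cal_slope,cal_intercept Named per-species true calibration
#'   coefficients (calibrated = slope * raw + intercept); the generator
#'   emits raw values through the inverse map.
#' @param channel Channel label, default `"bottom"`.
#' @param start First cycle start (POSIXct UTC).
#' @return A `boreq_campaign_config` list.
#' @export
campaign_config <- function(duration_h = 240, sampling_interval_h = 3,
                            cycle_length_s = 900, sample_period_s = 5,
                            liquid_pre = c(O18 = -8.43, H2 = -59.28),
                            liquid_post = c(O18 = -9.22, H2 = 297.57),
                            switch_time_h = 96, transition_tau_h = 12,
                            transition_shape = c("exponential", "logistic"),
                            t_stem_mean_c = 16.8, t_stem_amplitude_c = 1.3,
                            t_stem_peak_hour = 15,
                            rh_true = 0.98, pressure_pa = .P0,
                            noise_sd = c(O18 = 0.25, H2 = 0.75),
                            h2o_noise_ppm = 20,
                            p_low_rh = 0.02, p_sd_burst = 0.02,
                            cal_slope = c(O18 = 1, H2 = 1),
                            cal_intercept = c(O18 = 0, H2 = 0),
                            channel = "bottom",
                            start = as.POSIXct("2018-11-15 00:00:00", tz = "UTC")) {
  transition_shape <- match.arg(transition_shape)
  cfg <- mget(setdiff(names(formals()), "transition_shape"))
  cfg$transition_shape <- transition_shape
  stopifnot(all(noise_sd >= 0), h2o_noise_ppm >= 0,
            p_low_rh >= 0, p_low_rh <= 1, p_sd_burst >= 0, p_sd_burst <= 1,
            rh_true > 0, rh_true <= 1, transition_tau_h > 0,
            switch_time_h >= 0, duration_h > 0)
  for (v in list(liquid_pre, liquid_post, noise_sd, cal_slope, cal_intercept))
    if (!all(BOREQ_SPECIES %in% names(v)))
      stop("per-species parameters must be named with ", paste(BOREQ_SPECIES, collapse = ", "))
  structure(cfg, class = "boreq_campaign_config")
}

## True liquid xylem delta at time t (hours from start) for one species.
.liquid_delta_at <- function(t_h, pre, post, switch_h, tau_h, shape) {
  if (shape == "exponential") {
    ifelse(t_h < switch_h, pre,
           pre + (post - pre) * (1 - exp(-(t_h - switch_h) / tau_h)))
  } else {
    pre + (post - pre) / (1 + exp(-(t_h - switch_h) / tau_h))
  }
}

#' Generate a synthetic measurement campaign
#'
#' Emits the per-sample raw series the instrument would record (same CSV
#' dialect [process_campaign()] consumes) together with a ground-truth list
#' sufficient to score every pipeline output. Identical seed and
#' configuration give identical output.
#'
#' @param config A [campaign_config()].
#' @param seed Integer random seed; the caller's RNG state is restored on
#'   exit.
#' @return A `boreq_campaign` list:
#'   * `samples`: data.frame `timestamp`, `channel`, `h2o_ppm`, `d18o_raw`,
#'     `d2h_raw`, `t_stem_c`, `pressure_pa`;
#'   * `truth`: liquid plateaus, switch time, transition shape and tau, the
#'     true liquid-delta midpoint crossing time (hours and POSIXct), true
#'     calibration coefficients, true RH, per-cycle artifact table, and the
#'     configuration.
#' @export
generate_campaign <- function(config, seed = 1L) {
  stopifnot(inherits(config, "boreq_campaign_config"))
  .with_seed(seed, {
    cfg <- config
    cycle_starts_h <- seq(0, cfg$duration_h, by = cfg$sampling_interval_h)
    n_cycles <- length(cycle_starts_h)
    offsets_s <- seq(0, cfg$cycle_length_s - cfg$sample_period_s, by = cfg$sample_period_s)
    n_per <- length(offsets_s)

    art_low_rh <- stats::runif(n_cycles) < cfg$p_low_rh
    art_burst <- stats::runif(n_cycles) < cfg$p_sd_burst
    rh_mult <- ifelse(art_low_rh, stats::runif(n_cycles, 0.55, 0.75), 1)

    t_h <- rep(cycle_starts_h, each = n_per) + rep(offsets_s, n_cycles) / 3600
    cycle_of <- rep(seq_len(n_cycles), each = n_per)
    hour_of_day <- (t_h + as.numeric(format(cfg$start, "%H", tz = "UTC"))) %% 24
    t_stem_c <- cfg$t_stem_mean_c + cfg$t_stem_amplitude_c *
      cos(2 * pi * (hour_of_day - cfg$t_stem_peak_hour) / 24)
    T_K <- t_stem_c + .T0

    w_sat <- saturation_mole_fraction(T_K, cfg$pressure_pa)
    w_true <- cfg$rh_true * rh_mult[cycle_of] * w_sat
    h2o_ppm <- w_true * 1e6 + stats::rnorm(length(t_h), 0, cfg$h2o_noise_ppm)

    burst_mult <- ifelse(art_burst, 3, 1)[cycle_of]
    raw <- list()
    for (sp in BOREQ_SPECIES) {
      liq <- .liquid_delta_at(t_h, cfg$liquid_pre[[sp]], cfg$liquid_post[[sp]],
                              cfg$switch_time_h, cfg$transition_tau_h,
                              cfg$transition_shape)
      vap <- liquid_to_vapor_delta(liq, sp, T_K)
      # invert the calibration map so that fitting recovers slope/intercept
      raw[[sp]] <- (vap - cfg$cal_intercept[[sp]]) / cfg$cal_slope[[sp]] +
        stats::rnorm(length(t_h), 0, cfg$noise_sd[[sp]] * burst_mult)
    }

    samples <- data.frame(
      timestamp = cfg$start + 3600 * t_h,
      channel = cfg$channel,
      h2o_ppm = h2o_ppm,
      d18o_raw = raw$O18,
      d2h_raw = raw$H2,
      t_stem_c = t_stem_c,
      pressure_pa = cfg$pressure_pa
    )

    midpoint_h <- if (cfg$transition_shape == "exponential") {
      cfg$switch_time_h + cfg$transition_tau_h * log(2)
    } else {
      cfg$switch_time_h
    }
    truth <- list(
      liquid_pre = cfg$liquid_pre, liquid_post = cfg$liquid_post,
      switch_time_h = cfg$switch_time_h, transition_tau_h = cfg$transition_tau_h,
      transition_shape = cfg$transition_shape,
      midpoint_time_h = midpoint_h,
      midpoint_time = cfg$start + 3600 * midpoint_h,
      cal_slope = cfg$cal_slope, cal_intercept = cfg$cal_intercept,
      rh_true = cfg$rh_true,
      artifacts = data.frame(cycle = seq_len(n_cycles),
                             start_h = cycle_starts_h,
                             low_rh = art_low_rh, sd_burst = art_burst),
      seed = seed, config = cfg
    )
    structure(list(samples = samples, truth = truth), class = "boreq_campaign")
  })
}

#' Generate synthetic headspace standards
#'
#' Produces a standards table in the dialect [fit_calibration()] consumes:
#' the measured values are the affine (inverse-calibration) transform of
#' each standard's equilibrium vapor target at the headspace temperature,
#' optionally with Gaussian noise.
#'
#' @param liquid_deltas data.frame `name`, `d18o_liquid`, `d2h_liquid`;
#'   defaults to the four-standard light/medium/heavy/label scheme.
#' @param t_headspace_c Headspace temperature (deg C) at sampling.
#' @param slope,intercept Named per-species true calibration coefficients
#'   (calibrated = slope * measured + intercept).
#' @param noise_sd Named per-species measurement noise SD (per mil),
#'   default 0 (noiseless).
#' @param seed Optional seed used when `noise_sd` is nonzero.
#' @return data.frame `name`, `d18o_liquid`, `d2h_liquid`,
#'   `t_headspace_c`, `d18o_meas`, `d2h_meas`.
#' @export
generate_standards <- function(liquid_deltas = NULL, t_headspace_c = 20,
                               slope = c(O18 = 1, H2 = 1),
                               intercept = c(O18 = 0, H2 = 0),
                               noise_sd = c(O18 = 0, H2 = 0), seed = NULL) {
  if (is.null(liquid_deltas)) liquid_deltas <- .DEFAULT_STANDARDS
  if (nrow(liquid_deltas) < 2L) stop("at least 2 standards are required")
  for (v in list(slope, intercept, noise_sd))
    if (!all(BOREQ_SPECIES %in% names(v)))
      stop("per-species parameters must be named with ", paste(BOREQ_SPECIES, collapse = ", "))
  gen <- function() {
    T_K <- t_headspace_c + .T0
    out <- data.frame(
      name = liquid_deltas$name,
      d18o_liquid = liquid_deltas$d18o_liquid,
      d2h_liquid = liquid_deltas$d2h_liquid,
      t_headspace_c = t_headspace_c,
      stringsAsFactors = FALSE
    )
    for (sp in BOREQ_SPECIES) {
      liq <- if (sp == "O18") out$d18o_liquid else out$d2h_liquid
      target <- liquid_to_vapor_delta(liq, sp, T_K)
      meas <- (target - intercept[[sp]]) / slope[[sp]] +
        stats::rnorm(nrow(out), 0, noise_sd[[sp]])
      out[[if (sp == "O18") "d18o_meas" else "d2h_meas"]] <- meas
    }
    out
  }
  if (is.null(seed)) gen() else .with_seed(seed, gen())
}

#' Write a synthetic campaign to disk
#'
#' Writes the raw samples as RFC 4180 CSV (ISO 8601 UTC timestamps) and the
#' ground truth as JSON, in the dialects the processing pipeline reads.
#'
#' @param campaign A [generate_campaign()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`raw`, `truth`).
#' @export
write_campaign <- function(campaign, dir) {
  stopifnot(inherits(campaign, "boreq_campaign"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  raw_path <- file.path(dir, "raw.csv")
  truth_path <- file.path(dir, "truth.json")
  s <- campaign$samples
  s$timestamp <- format(s$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(s, raw_path, row.names = FALSE)
  truth <- campaign$truth
  truth$midpoint_time <- format(truth$midpoint_time, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  truth$config$start <- format(truth$config$start, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(raw = raw_path, truth = truth_path))
}
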