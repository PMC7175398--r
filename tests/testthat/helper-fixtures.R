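# Shared fixture builders for the test suite.

# The worked "modeling" configuration: 10 mm borehole, 0.10 m wetted length,
# 40 mL/min, 10 degC, xylem -15/-120 per mil, inflow -20/-150 at 50% RH.
worked_env <- function() env_conditions(283.15)
worked_geom <- function() borehole_geometry(0.005, wetted_length_m = 0.10)
worked_flow <- function(ml_min = 40) airflow(ml_min_to_m3_s(ml_min))
worked_xylem <- function() xylem_source(c(O18 = -15, H2 = -120))
worked_inflow <- function(rh = 0.5, env = worked_env()) {
  vapor_parcel(rh = rh, delta = c(O18 = -20, H2 = -150), env = env)
}

# Freiburg-style bottom-borehole configuration: 9.9 cm stem, 80 mL/min, 16.8 degC.
freiburg_env <- function() env_conditions(289.95)
freiburg_geom <- function() borehole_geometry(0.005, stem_diameter_m = 0.099)
freiburg_flow <- function(convention = "centerline_double") {
  airflow(ml_min_to_m3_s(80), velocity_convention = convention)
}

# Random valid model configuration for property-style tests; assumes the
# caller controls the RNG seed.
random_model_draw <- function() {
  T_K <- runif(1, 275, 305)
  env <- env_conditions(T_K)
  geom <- borehole_geometry(runif(1, 0.001, 0.01), wetted_length_m = runif(1, 0.02, 0.3))
  flow <- airflow(runif(1, 1e-7, 1e-5))
  w_sat <- saturation_mole_fraction(T_K)
  inflow <- vapor_parcel(w = runif(1, 0, 0.95) * w_sat,
                         delta = c(O18 = runif(1, -30, 0), H2 = runif(1, -200, 0)))
  xylem <- xylem_source(c(O18 = runif(1, -25, 0), H2 = runif(1, -180, 0)))
  list(env = env, geom = geom, flow = flow, inflow = inflow, xylem = xylem)
}

# A small noiseless, artifact-free campaign whose post-switch plateau is
# effectively reached (switch + 8 tau < end of record).
clean_campaign_config <- function(...) {
  args <- utils::modifyList(
    list(duration_h = 120, switch_time_h = 24, transition_tau_h = 6,
         noise_sd = c(O18 = 0, H2 = 0), h2o_noise_ppm = 0,
         p_low_rh = 0, p_sd_burst = 0),
    list(...))
  do.call(campaign_config, args)
}
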