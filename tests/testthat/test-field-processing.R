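# Cycle averaging, QC, calibration, vapor->liquid conversion, breakthrough timing.

make_cycle <- function(values_o18, t0 = as.POSIXct("2020-01-01 00:00:00", tz = "UTC"),
                       period_s = 5, h2o = 12000, t_stem = 16.8) {
  n <- length(values_o18)
  data.frame(
    timestamp = t0 + period_s * (seq_len(n) - 1L),
    channel = "bottom",
    h2o_ppm = rep_len(h2o, n),
    d18o_raw = values_o18,
    d2h_raw = values_o18 * 8,  # arbitrary companion series
    t_stem_c = rep_len(t_stem, n),
    pressure_pa = 101325
  )
}

test_that("trailing-window averaging uses only the end of the cycle", {
  cyc <- make_cycle(rep(-24, 180))  # 15 min at 5 s
  rec <- average_cycle(cyc, window_s = 180)
  expect_equal(rec$d18o_raw_mean, -24)
  expect_equal(rec$d18o_raw_sd, 0)
  expect_equal(rec$n_window, 37)  # 180 s inclusive window at 5 s cadence
  # step halfway through the cycle: the 3-min trailing window sees only the
  # post-step value
  step <- make_cycle(c(rep(-30, 90), rep(-20, 90)))
  rec2 <- average_cycle(step, window_s = 180)
  expect_equal(rec2$d18o_raw_mean, -20)
  expect_equal(rec2$d18o_raw_sd, 0)
  # too few samples in the window -> short-cycle flag
  tiny <- make_cycle(c(-24, -24), period_s = 200)
  rec3 <- average_cycle(tiny, window_s = 180)
  expect_true(rec3$flag_short_cycle)
})

test_that("cycles are split on flush gaps with no silent data loss", {
  c1 <- make_cycle(rep(-24, 60))
  c2 <- make_cycle(rep(-22, 60), t0 = as.POSIXct("2020-01-01 03:00:00", tz = "UTC"))
  raw <- rbind(c2, c1)  # deliberately out of order
  split <- split_cycles(raw)
  expect_identical(length(unique(split$cycle_id)), 2L)
  expect_identical(nrow(split), nrow(raw))
  recs <- average_cycles(raw, window_s = 180)
  expect_identical(nrow(recs), 2L)
  expect_equal(recs$d18o_raw_mean, c(-24, -22))
})

test_that("QC thresholds flag on exclusive boundaries and keep every record", {
  recs <- data.frame(
    d18o_raw_sd = c(0.6, 0.5, 0.2, 0.2, 0.2),
    d2h_raw_sd = c(0.2, 0.2, 1.6, 1.5, 0.2),
    rh = c(0.95, 0.95, 0.95, 0.80, 0.79)
  )
  out <- qc_filter(recs)
  expect_identical(out$flag_sd_o18, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_identical(out$flag_sd_h2, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_identical(out$flag_low_rh, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_identical(out$qc_pass, c(FALSE, TRUE, FALSE, TRUE, FALSE))
  s <- qc_summary(out)
  expect_identical(s$n_excluded + s$n_clean, s$n_cycles)
  expect_equal(s$pct_excluded, 60)
})

test_that("borehole relative humidity is w/w_sat with a condensation warning", {
  w_sat <- saturation_mole_fraction(283.15, 101325)
  expect_equal(borehole_rh(w_sat, 283.15), 1.0)
  expect_equal(borehole_rh(0, 283.15), 0.0)
  expect_equal(borehole_rh(0.9 * w_sat, 283.15), 0.90, tolerance = 1e-12)
  expect_warning(borehole_rh(1.1 * w_sat, 283.15), "condensation")
})

test_that("calibration against standards recovers known instrument transforms", {
  # measured exactly at target -> identity mapping
  std <- generate_standards()
  cal <- fit_calibration(std)
  for (sp in BOREQ_SPECIES) {
    expect_equal(cal$coefficients[[sp]][["slope"]], 1, tolerance = 1e-10)
    expect_equal(cal$coefficients[[sp]][["intercept"]], 0, tolerance = 1e-10)
  }
  # a constant 1.12 per mil lighter reading is corrected by +1.12
  std_off <- std
  std_off$d2h_meas <- std_off$d2h_meas - 1.12
  cal_off <- fit_calibration(std_off)
  expect_equal(cal_off$coefficients$H2[["intercept"]], 1.12, tolerance = 1e-9)
  expect_equal(calibrate_delta(-100, cal_off, "H2", warn_extrapolation = FALSE),
               -100 + 1.12, tolerance = 1e-9)
  # two standards with a known slope: exact interpolation
  std2 <- generate_standards(liquid_deltas = data.frame(
    name = c("a", "b"), d18o_liquid = c(-20, 0), d2h_liquid = c(-150, 0)),
    slope = c(O18 = 0.98, H2 = 0.98), intercept = c(O18 = 0.3, H2 = -2))
  cal2 <- fit_calibration(std2)
  expect_equal(cal2$coefficients$O18[["slope"]], 0.98, tolerance = 1e-10)
  expect_equal(cal2$coefficients$H2[["intercept"]], -2, tolerance = 1e-10)
  expect_error(fit_calibration(std[1, ]), "at least 2")
})

test_that("breakthrough midpoint timing recovers symmetric and step transitions", {
  t <- seq(0, 48, by = 0.5)
  logi <- -24 + 10 / (1 + exp(-(t - 20) / 2))
  bt <- breakthrough_midpoint(t, logi, pre_window = c(0, 6), post_window = c(40, 48))
  expect_equal(bt$midpoint, (bt$initial + bt$final) / 2)
  expect_equal(bt$crossing_time, 20, tolerance = 0.02)
  # step function: crossing interpolated within the step interval
  stepv <- ifelse(t < 20, -24, -14)
  bt2 <- breakthrough_midpoint(t, stepv, pre_window = c(0, 6), post_window = c(40, 48))
  expect_gte(bt2$crossing_time, 19.5); expect_lte(bt2$crossing_time, 20)
  # falling transitions work too
  bt3 <- breakthrough_midpoint(t, -logi, pre_window = c(0, 6), post_window = c(40, 48))
  expect_equal(bt3$crossing_time, 20, tolerance = 0.02)
  expect_equal(bt3$direction, -1)
  # POSIXct time in, POSIXct crossing out
  tp <- as.POSIXct("2020-01-01", tz = "UTC") + 3600 * t
  bt4 <- breakthrough_midpoint(tp, logi, pre_window = tp[c(1, 13)], post_window = tp[c(81, 97)])
  expect_s3_class(bt4$crossing_time, "POSIXct")
  # transition samples all missing (e.g. QC-excluded) -> not-found error
  gappy <- ifelse(t < 10, -24, ifelse(t > 38, -14, NA_real_))
  expect_error(breakthrough_midpoint(t, gappy, pre_window = c(0, 6), post_window = c(40, 48)),
               "never crosses")
})

test_that("lag velocity and predicted arrival follow the defining arithmetic", {
  expect_equal(velocity_from_lag(0.50, 70, 124), 50 / 54, tolerance = 1e-12)
  expect_equal(velocity_from_lag(0.50, 70, 124), 0.93, tolerance = 0.005)
  expect_equal(velocity_from_lag(1.0, 10, 20), 2 * velocity_from_lag(0.5, 10, 20))
  expect_error(velocity_from_lag(0.5, 124, 70), "later")
  # 0.40 m at 1 m per 12-h day
  expect_equal(predicted_arrival(0.40, 100 / 12), 4.8, tolerance = 1e-12)
})

test_that("linear calibration commutes with cycle averaging", {
  cyc <- make_cycle(-24 + sin(1:180))
  cal <- fit_calibration(generate_standards(slope = c(O18 = 0.97, H2 = 1.02),
                                            intercept = c(O18 = 0.4, H2 = -1.1)))
  # calibrate per sample, then average
  cyc_cal <- cyc
  cyc_cal$d18o_raw <- calibrate_delta(cyc$d18o_raw, cal, "O18", warn_extrapolation = FALSE)
  a <- average_cycle(cyc_cal, window_s = 180)$d18o_raw_mean
  # average, then calibrate
  b <- calibrate_delta(average_cycle(cyc, window_s = 180)$d18o_raw_mean, cal, "O18",
                       warn_extrapolation = FALSE)
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("the full pipeline recovers a synthetic campaign's ground truth", {
  cfg <- campaign_config(duration_h = 150, switch_time_h = 30, transition_tau_h = 6,
                         p_low_rh = 0.05, p_sd_burst = 0.05)
  camp <- generate_campaign(cfg, seed = 101)
  std <- generate_standards()
  res <- process_campaign(camp$samples, std)
  expect_s3_class(res, "boreq_processed")
  # no silent data loss
  s <- res$report$qc
  expect_identical(s$n_excluded + s$n_clean, s$n_cycles)
  recs <- res$records[res$records$qc_pass, ]
  t_h <- as.numeric(difftime(recs$cycle_end, cfg$start, units = "hours"))
  # plateau recovery within 2 standard errors of the clean-cycle mean
  pre <- recs$d2h_liquid[t_h < cfg$switch_time_h]
  post <- recs$d2h_liquid[t_h > cfg$switch_time_h + 8 * cfg$transition_tau_h]
  expect_lt(abs(mean(pre) - cfg$liquid_pre[["H2"]]), 2 * sd(pre) / sqrt(length(pre)) + 0.05)
  expect_lt(abs(mean(post) - cfg$liquid_post[["H2"]]), 2 * sd(post) / sqrt(length(post)) + 0.05)
  # arrival time within two sampling intervals of the true midpoint crossing
  bt <- breakthrough_midpoint(t_h, recs$d2h_liquid, pre_window = c(0, cfg$switch_time_h - 3),
                              post_window = c(cfg$switch_time_h + 8 * cfg$transition_tau_h, max(t_h)))
  expect_lt(abs(bt$crossing_time - camp$truth$midpoint_time_h), 2 * cfg$sampling_interval_h)
})
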