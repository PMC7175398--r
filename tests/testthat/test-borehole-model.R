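# Time constants, per-segment closed forms, and the chained simulation.

test_that("diffusion time reproduces the worked value and scales with r^2", {
  env <- worked_env()
  expect_equal(diffusion_time(worked_geom(), env), 0.28, tolerance = 0.005 / 0.28)
  g_half <- borehole_geometry(0.0025, wetted_length_m = 0.10)
  expect_equal(diffusion_time(g_half, env), diffusion_time(worked_geom(), env) / 4)
  # at standard conditions D = D0 exactly
  expect_equal(diffusion_time(worked_geom(), env_conditions(273.15)),
               2.5e-5 / (4 * 2.12e-5))
})

test_that("turnover time matches the worked and tabulated boreholes", {
  expect_equal(turnover_time(worked_geom(), worked_flow(40)), 5.9, tolerance = 0.01 / 5.9)
  top <- borehole_geometry(0.005, stem_diameter_m = 0.08)
  expect_equal(top$wetted_length_m, 0.06)  # stem diameter minus 2 cm fittings
  expect_equal(turnover_time(top, freiburg_flow()), 1.77, tolerance = 0.005 / 1.77)
  expect_equal(turnover_time(freiburg_geom(), freiburg_flow()), 2.33, tolerance = 0.005 / 2.33)
})

test_that("vapor time constant matches the tabulated values and its low-flow limit", {
  env <- freiburg_env()
  expect_equal(vapor_time_constant(freiburg_geom(), freiburg_flow("mean"), env),
               0.47, tolerance = 0.005 / 0.47)
  top <- borehole_geometry(0.005, stem_diameter_m = 0.08)
  expect_equal(vapor_time_constant(top, freiburg_flow("mean"), env),
               0.46, tolerance = 0.005 / 0.46)
  # Q -> 0: t_w -> r^2/(2D), independent of wetted length
  tw0 <- vapor_time_constant(freiburg_geom(), airflow(1e-12, "mean"), env)
  expect_equal(tw0, 0.005^2 / (2 * vapor_diffusivity(env)), tolerance = 1e-6)
})

test_that("isotope time constants collapse to t_w iff alpha_k is 1", {
  env <- freiburg_env()
  geom <- freiburg_geom()
  flow <- freiburg_flow()
  w_sat <- saturation_mole_fraction(env$temperature_K)
  tc1 <- isotope_time_constants(geom, flow, env, w_i = 0.5 * w_sat, alpha_k = 1)
  expect_equal(unname(tc1$t_x_x[["O18"]]), tc1$t_w, tolerance = 1e-12)
  tc <- isotope_time_constants(geom, flow, env, w_i = 0.5 * w_sat)
  expect_true(all(tc$t_x_x > tc$t_w))
  # saturated borehole: no net evaporation, Craig-Gordon constant diverges
  tcs <- isotope_time_constants(geom, flow, env, w_i = w_sat, w_o = w_sat)
  expect_true(all(is.infinite(tcs$t_x_C)) ||
                all(tcs$t_x_C > geom$volume_m3 * 1e3))
  expect_error(isotope_time_constants(geom, flow, env, w_i = 0.5 * w_sat, w_o = 1.1 * w_sat),
               "condensation")
})

test_that("t_x,x >= t_w with equality iff alpha_k = 1 over random draws", {
  set.seed(42)
  n_eq <- 0L
  for (i in 1:1000) {
    d <- random_model_draw()
    w_sat <- saturation_mole_fraction(d$env$temperature_K)
    ak <- if (i %% 4 == 0) 1 else runif(1, 1 + 1e-6, 1.06)
    tc <- isotope_time_constants(d$geom, d$flow, d$env, w_i = d$inflow$w, alpha_k = ak)
    if (ak == 1) {
      expect_equal(unname(tc$t_x_x[["O18"]]), tc$t_w, tolerance = 1e-10)
      n_eq <- n_eq + 1L
    } else {
      expect_gt(min(tc$t_x_x), tc$t_w)
    }
  }
  expect_gt(n_eq, 200L)  # both branches actually exercised
})

test_that("segment vapor steady state is the conductance-weighted mean", {
  env <- worked_env()
  geom <- worked_geom()
  w_sat <- saturation_mole_fraction(env$temperature_K)
  # fixed point at saturation
  expect_equal(segment_vapor_steady_state(w_sat, geom, worked_flow(), env), w_sat)
  # diffusion-dominated limit from dry air
  expect_equal(segment_vapor_steady_state(0, geom, airflow(1e-13), env), w_sat,
               tolerance = 1e-6)
  # equal weights: carrier flow set equal to the volumetric wall conductance
  gv <- 2 * pi * geom$wetted_length_m * vapor_diffusivity(env)
  fl_eq <- airflow(gv, velocity_convention = "mean")
  expect_equal(segment_vapor_steady_state(0.5 * w_sat, geom, fl_eq, env),
               0.75 * w_sat, tolerance = 1e-12)
  # strictly between w_i and w_sat otherwise
  w <- segment_vapor_steady_state(0.2 * w_sat, geom, worked_flow(), env)
  expect_gt(w, 0.2 * w_sat); expect_lt(w, w_sat)
})

test_that("exponential relaxation kernel has the right fixed points and semigroup", {
  expect_identical(segment_vapor_step(0.4, 0, 1, 2), 0.4)
  expect_equal(segment_vapor_step(0, log(2) * 3, 1, 3), 0.5)
  # n small steps == one big step
  x <- 0.1
  for (i in 1:10) x <- segment_vapor_step(x, 0.05, 0.9, 0.7)
  expect_equal(x, segment_vapor_step(0.1, 0.5, 0.9, 0.7), tolerance = 1e-12)
  expect_error(segment_vapor_step(0, -1, 1, 1), "non-negative")
})

test_that("surface composition implements the three wall closures", {
  env <- worked_env()
  xy <- worked_xylem()
  w_sat <- saturation_mole_fraction(env$temperature_K)
  parcel <- vapor_parcel(w = 0.5 * w_sat, delta = c(O18 = -24, H2 = -170))
  ap <- sapply(BOREQ_SPECIES, equilibrium_alpha, temperature_K = env$temperature_K)
  # fixed xylem equilibrium: R_x / alpha+
  s1 <- surface_composition(surface_model("xylem_equilibrium"), xy, parcel, env)
  expect_equal(s1, xy$ratio / ap, tolerance = 1e-15)
  # Craig-Gordon with dry borehole air: alpha_k * R_x
  dry <- vapor_parcel(w = 0, delta = c(O18 = 0, H2 = 0))
  s2 <- surface_composition(surface_model("craig_gordon"), xy, dry, env)
  expect_equal(unname(s2), unname(c(O18 = 1.0285, H2 = 1.0251) * xy$ratio), tolerance = 1e-12)
  # Craig-Gordon at saturation degenerates to equilibrium with the vapor
  satp <- vapor_parcel(w = w_sat, delta = c(O18 = -24, H2 = -170))
  s3 <- surface_composition(surface_model("craig_gordon"), xy, satp, env)
  expect_equal(s3, satp$ratio[BOREQ_SPECIES])
  # mixture endpoints
  s_f1 <- surface_composition(surface_model("mixed", f = 1), xy, parcel, env)
  s_f0 <- surface_composition(surface_model("mixed", f = 0), xy, parcel, env)
  expect_identical(s_f1, s1)
  expect_identical(s_f0, surface_composition(surface_model("craig_gordon"), xy, parcel, env))
})

test_that("segment isotope steady state reduces to a weighted mean when alpha_k = 1", {
  env <- worked_env()
  geom <- worked_geom()
  flow <- worked_flow()
  xy <- worked_xylem()
  w_sat <- saturation_mole_fraction(env$temperature_K)
  w_i <- 0.4 * w_sat
  w_o <- segment_vapor_steady_state(w_i, geom, flow, env)
  R_i <- delta_to_ratio(c(O18 = -22, H2 = -160))
  R_o <- segment_isotope_steady_state(surface_model("xylem_equilibrium"),
                                      w_i, R_i, w_o, xy, geom, flow, env, alpha_k = 1)
  # independent oracle: flux-weighted mean of inflow and wall-equilibrium vapor
  u <- 2 * flow$Q_m3_s / molar_volume(env)
  g <- 2 * pi * geom$wetted_length_m * vapor_diffusivity(env) / molar_volume(env)
  ap <- sapply(BOREQ_SPECIES, equilibrium_alpha, temperature_K = env$temperature_K)
  oracle <- (u * w_i * R_i + g * w_sat * xy$ratio / ap) / (u * w_i + g * w_sat)
  expect_equal(R_o, oracle, tolerance = 1e-12)
  # Craig-Gordon at saturation: no evaporation, composition passes through
  R_sat <- segment_isotope_steady_state(surface_model("craig_gordon"),
                                        w_sat, R_i, w_sat, xy, geom, flow, env)
  expect_equal(R_sat, R_i[BOREQ_SPECIES], tolerance = 1e-12)
  # global fixed point: inflow already at R_x/alpha+ with alpha_k = 1
  R_eq <- xy$ratio / ap
  R_fp <- segment_isotope_steady_state(surface_model("xylem_equilibrium"),
                                       w_sat, R_eq, w_sat, xy, geom, flow, env, alpha_k = 1)
  expect_equal(R_fp, R_eq, tolerance = 1e-12)
})

test_that("dry-air inflow correction follows von Caemmerer-Farquhar", {
  expect_equal(dry_air_inflow_correction(2.5, 0.01, 0.01), 2.5)
  expect_equal(dry_air_inflow_correction(1.0, 0.0, 0.012), 0.988)
  w_o <- seq(0, 0.05, by = 0.01)
  expect_true(all(diff(dry_air_inflow_correction(1, 0.01, w_o)) < 0))
  expect_error(dry_air_inflow_correction(1, 1.2, 0.01), "\\[0, 1\\)")
})

test_that("an N=1 simulation equals the analytic single-segment formulas", {
  env <- worked_env()
  geom <- worked_geom()
  flow <- worked_flow()
  xy <- worked_xylem()
  inflow <- worked_inflow()
  for (surf in list(surface_model("xylem_equilibrium"), surface_model("craig_gordon"),
                    surface_model("mixed", f = 0.35))) {
    sim <- simulate_borehole(geom, flow, env, inflow, xy, surface = surf, N = 1,
                             check_convergence = FALSE)
    w_o <- segment_vapor_steady_state(inflow$w, geom, flow, env)
    R_o <- segment_isotope_steady_state(surf, inflow$w, inflow$ratio, w_o, xy,
                                        geom, flow, env)
    expect_equal(sim$segments$w, w_o, tolerance = 1e-12)
    expect_equal(sim$outlet$delta, ratio_to_delta(R_o), tolerance = 1e-12)
  }
})

test_that("the segment chain conserves water mass to 1e-10 for all closures", {
  set.seed(7)
  for (i in 1:40) {
    d <- random_model_draw()
    surf <- list(surface_model("xylem_equilibrium"), surface_model("craig_gordon"),
                 surface_model("mixed", f = runif(1)))[[1 + i %% 3]]
    N <- sample(c(1, 3, 17, 100, 500), 1)
    sim <- simulate_borehole(d$geom, d$flow, d$env, d$inflow, d$xylem,
                             surface = surf, N = N, check_convergence = FALSE)
    expect_lt(sim$mass_balance_residual, 1e-10)
  }
})

test_that("humidity increases monotonically along the borehole and saturates", {
  env <- worked_env()
  sim <- simulate_borehole(worked_geom(), worked_flow(), env, worked_inflow(rh = 0.2),
                           worked_xylem(), N = 300, check_convergence = FALSE)
  expect_true(all(diff(sim$segments$h) > 0))
  expect_true(all(sim$segments$h <= 1 + 1e-12))
  # long-borehole / low-flow limit: outlet humidity -> 1
  long <- borehole_geometry(0.005, wetted_length_m = 2)
  sim_long <- simulate_borehole(long, worked_flow(), env, worked_inflow(rh = 0.2),
                                worked_xylem(), N = 400, check_convergence = FALSE)
  expect_gt(sim_long$segments$h[400], 0.999)
  sim_slow <- simulate_borehole(worked_geom(), airflow(1e-9), env, worked_inflow(rh = 0.2),
                                worked_xylem(), N = 300, check_convergence = FALSE)
  expect_gt(sim_slow$segments$h[300], 0.999)
})

test_that("saturated inflow at wall equilibrium is a global fixed point", {
  env <- worked_env()
  xy <- worked_xylem()
  w_sat <- saturation_mole_fraction(env$temperature_K)
  d_eq <- sapply(BOREQ_SPECIES, function(sp) liquid_to_vapor_delta(xy$delta[[sp]], sp, env$temperature_K))
  inflow <- vapor_parcel(w = w_sat, delta = d_eq)
  for (surf in list(surface_model("xylem_equilibrium"), surface_model("craig_gordon"),
                    surface_model("mixed", f = 0.5))) {
    sim <- simulate_borehole(worked_geom(), worked_flow(), env, inflow, xy,
                             surface = surf, N = 50, alpha_k = 1, check_convergence = FALSE)
    expect_equal(sim$outlet$w, w_sat, tolerance = 1e-14)
    expect_equal(sim$outlet$delta, d_eq, tolerance = 1e-10)
  }
})

test_that("super-saturated inflow is rejected as a condensation regime", {
  env <- worked_env()
  w_sat <- saturation_mole_fraction(env$temperature_K)
  wet <- vapor_parcel(w = 1.1 * w_sat, delta = c(O18 = -20, H2 = -150))
  expect_error(simulate_borehole(worked_geom(), worked_flow(), env, wet, worked_xylem()),
               "condensation")
})

test_that("the convergence guard warns on an under-resolved grid", {
  env <- worked_env()
  expect_warning(
    simulate_borehole(worked_geom(), worked_flow(), env, worked_inflow(),
                      worked_xylem(), surface = surface_model("mixed", f = 0.35), N = 4),
    "not converged")
})
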