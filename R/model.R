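## Segmented steady-state model of water vapor and its isotopic composition
## in air traversing a stem borehole.
##
## Per segment of wetted length dl, the molar balance of vapor is
##   V~ dw/dt = u_o (w_i - w_o) + A~ (D/r) (w_sat - w_o)
## and of the heavy isotopologue
##   V~ d(w R)/dt = u_o (w_i R_i - w_o R_o) + A~ (D/r) (1/alpha_k) (w_sat R_s - w_o R_o)
## where A~ (D/r) = 2 pi dl D / V_1mol is independent of the radius. The
## kinetic factor divides the wall-exchange term (diffusion passes heavy
## isotopologues more slowly); this reading is the one consistent with the
## closed-form steady states and with t_x,x >= t_w, equality iff alpha_k = 1.

## Molar wall-exchange conductance A~ D / r = 2 pi l D / V_1mol (mol/s) for a
## (segment of) wetted length l.
.wall_conductance <- function(wetted_length_m, env) {
  2 * pi * wetted_length_m * vapor_diffusivity(env) / molar_volume(env)
}

.alpha_k_vec <- function(alpha_k = NULL) {
  out <- .ALPHA_K_DEFAULT
  if (!is.null(alpha_k)) {
    if (length(alpha_k) == 1L && is.null(names(alpha_k))) {
      out[] <- alpha_k
    } else {
      if (is.null(names(alpha_k)) || !all(names(alpha_k) %in% BOREQ_SPECIES))
        stop("alpha_k must be a single value or named with species ", paste(BOREQ_SPECIES, collapse = ", "))
      out[names(alpha_k)] <- alpha_k
    }
  }
  if (any(out < 1)) stop("alpha_k must be >= 1")
  out
}

#' Characteristic time for radial diffusion in the borehole
#'
#' `t_d = r^2 / (4 D)`: the time for water vapor to diffuse between the
#' wetted wall and the center of the laminar air stream. Equilibration is
#' plausible when the turnover time [turnover_time()] is much larger.
#'
#' @param geom A [borehole_geometry()] object.
#' @param env A [env_conditions()] object.
#' @return Time (s).
#' @examples
#' g <- borehole_geometry(0.005, wetted_length_m = 0.10)
#' diffusion_time(g, env_conditions(283.15))  # about 0.28 s
#' @export
diffusion_time <- function(geom, env) {
  geom$radius_m^2 / (4 * vapor_diffusivity(env))
}

#' Turnover time of the borehole air volume
#'
#' `t_u = V / u_carrier`: the residence time of the carrier air stream in the
#' borehole. Under the default `"centerline_double"` convention the carrier
#' flow is twice the observed mean flow (parabolic laminar profile), giving
#' `t_u = pi r^2 l / (2 Q)`; temperature drops out of the volumetric form.
#'
#' @param geom A [borehole_geometry()] object.
#' @param flow An [airflow()] object.
#' @return Time (s).
#' @examples
#' g <- borehole_geometry(0.005, wetted_length_m = 0.10)
#' turnover_time(g, airflow(ml_min_to_m3_s(40)))  # about 5.9 s
#' @export
turnover_time <- function(geom, flow) {
  geom$volume_m3 / .carrier_flow(flow)
}

#' Relaxation time constant of the borehole vapor mole fraction
#'
#' `t_w = V~ / (u_o + A~ D / r)`, evaluated volumetrically as
#' `pi r^2 l / (Q_carrier + 2 pi l D)`: the e-folding time with which the
#' whole-borehole vapor mole fraction approaches its steady state, driven by
#' both throughflow and wall exchange.
#'
#' @param geom A [borehole_geometry()] object.
#' @param flow An [airflow()] object; the `velocity_convention` sets
#'   `Q_carrier` (2Q or Q).
#' @param env A [env_conditions()] object.
#' @return Time (s).
#' @export
vapor_time_constant <- function(geom, flow, env) {
  geom$volume_m3 / (.carrier_flow(flow) + 2 * pi * geom$wetted_length_m * vapor_diffusivity(env))
}

#' Isotope relaxation time constants of the borehole vapor
#'
#' Time constants for the isotopic composition of the borehole vapor under
#' the two limiting wall closures:
#' `t_x,x = V~ w_o / (u_o w_i + A~ (D/r) (w_sat - (1 - 1/alpha_k) w_o))`
#' for a wall fixed at xylem equilibrium, and
#' `t_x,C = V~ w_o / (u_o w_i + A~ E)` with evaporation
#' `E = (D/r)(w_sat - w_o)` for a Craig-Gordon wall. It holds that
#' `t_x,x >= t_w` with equality iff `alpha_k = 1` when `w_o` is at its
#' steady state.
#'
#' @param geom,flow,env Geometry, airflow and conditions (see
#'   [borehole_geometry()], [airflow()], [env_conditions()]).
#' @param w_i Inflow vapor mole fraction.
#' @param w_o Borehole vapor mole fraction; defaults to the whole-borehole
#'   steady state for `w_i`. Must not exceed saturation.
#' @param alpha_k Kinetic fractionation: a single value or named per-species
#'   vector; defaults to the package defaults (see [kinetic_alpha()]).
#' @return A list with `t_w` (s) and named per-species vectors `t_x_x` and
#'   `t_x_C` (s; `t_x_C` is `Inf` when `w_o = w_sat`, where evaporation
#'   vanishes and only throughflow drives the isotopes).
#' @export
isotope_time_constants <- function(geom, flow, env, w_i, w_o = NULL, alpha_k = NULL) {
  ak <- .alpha_k_vec(alpha_k)
  w_sat <- saturation_mole_fraction(env$temperature_K, env$pressure_Pa)
  Qc <- .carrier_flow(flow)                        # volumetric carrier flow
  gv <- 2 * pi * geom$wetted_length_m * vapor_diffusivity(env)  # volumetric wall conductance
  if (is.null(w_o)) w_o <- (Qc * w_i + gv * w_sat) / (Qc + gv)
  if (w_o > w_sat + 1e-12)
    stop("w_o exceeds saturation: condensation regime, not modeled")
  V <- geom$volume_m3
  t_x_x <- V * w_o / (Qc * w_i + gv * (w_sat - (1 - 1 / ak) * w_o))
  denomC <- Qc * w_i + gv * (w_sat - w_o)
  t_x_C <- if (denomC > 0) rep(V * w_o / denomC, length(ak)) else rep(Inf, length(ak))
  names(t_x_C) <- names(ak)
  list(t_w = vapor_time_constant(geom, flow, env), t_x_x = t_x_x, t_x_C = t_x_C)
}

#' Steady-state vapor mole fraction of one borehole segment
#'
#' The conductance-weighted mean of the incoming mole fraction and the
#' saturation value at the wall:
#' `w_o^ss = (u_o w_i + A~ (D/r) w_sat) / (u_o + A~ (D/r))`.
#'
#' @param w_i Incoming vapor mole fraction in `[0, 1)`.
#' @param geom Segment geometry (a [borehole_geometry()] whose
#'   `wetted_length_m` is the segment length).
#' @param flow,env Airflow and conditions.
#' @return Steady-state mole fraction, strictly between `w_i` and `w_sat`
#'   when they differ.
#' @export
segment_vapor_steady_state <- function(w_i, geom, flow, env) {
  if (w_i < 0 || w_i >= 1) stop("w_i must lie in [0, 1)")
  w_sat <- saturation_mole_fraction(env$temperature_K, env$pressure_Pa)
  Qc <- .carrier_flow(flow)
  gv <- 2 * pi * geom$wetted_length_m * vapor_diffusivity(env)
  (Qc * w_i + gv * w_sat) / (Qc + gv)
}

#' Exponential relaxation toward a steady state
#'
#' The non-steady-state kernel shared by the vapor mole fraction and the
#' isotope ratio of a segment:
#' `x(t + dt) = x_ss + (x(t) - x_ss) exp(-dt / tau)`.
#'
#' @param x_t Current value.
#' @param dt Time step (s), `>= 0`.
#' @param x_ss Steady-state value.
#' @param tau Time constant (s), positive.
#' @return Value after `dt`.
#' @export
segment_vapor_step <- function(x_t, dt, x_ss, tau) {
  if (any(dt < 0)) stop("dt must be non-negative")
  if (any(tau <= 0)) stop("time constant must be positive")
  x_ss + (x_t - x_ss) * exp(-dt / tau)
}

#' Isotopic composition of the vapor at the borehole wall surface
#'
#' Returns the surface vapor ratio `R_s` for each species under the chosen
#' closure (see [surface_model()]). For the Craig-Gordon closure the surface
#' film has enriched until the net evaporated flux carries the xylem
#' composition, i.e. `R_s` solves
#' `(w_sat R_s - w_o R_o) / alpha_k = R_x (w_sat - w_o)`; at saturation
#' (`w_o = w_sat`, no net evaporation) the film is in equilibrium with the
#' borehole vapor and `R_s = R_o`.
#'
#' @param surface A [surface_model()] object.
#' @param xylem A [xylem_source()] object.
#' @param parcel A [vapor_parcel()] describing the borehole vapor (its `w`
#'   is `w_o`, its `ratio` is `R_o`).
#' @param env A [env_conditions()] object (sets `w_sat` and `alpha+`).
#' @param alpha_k Kinetic fractionation override (single value or named
#'   per-species vector).
#' @return Named per-species vector of normalized surface vapor ratios.
#' @export
surface_composition <- function(surface, xylem, parcel, env, alpha_k = NULL) {
  ak <- .alpha_k_vec(alpha_k)
  w_sat <- saturation_mole_fraction(env$temperature_K, env$pressure_Pa)
  ap <- vapply(BOREQ_SPECIES, equilibrium_alpha, numeric(1), temperature_K = env$temperature_K)
  R_x <- xylem$ratio[BOREQ_SPECIES]
  R_o <- parcel$ratio[BOREQ_SPECIES]
  w_o <- parcel$w
  if (w_o > w_sat + 1e-12) stop("parcel is super-saturated: condensation regime, not modeled")
  S_eq <- R_x / ap
  S_cg <- if (abs(w_sat - w_o) <= .Machine$double.eps * w_sat) {
    R_o
  } else {
    (ak * R_x * (w_sat - w_o) + w_o * R_o) / w_sat
  }
  surface$f * S_eq + (1 - surface$f) * S_cg
}

#' Steady-state isotope ratio of one borehole segment
#'
#' Closed-form steady state of the heavy-isotopologue balance for a segment
#' whose vapor mole fraction is already at its steady state `w_o`:
#' \deqn{R_o = \frac{u_o w_i R_i + (g f/\alpha_k)\, w_{sat} R_x/\alpha^+
#'   + g (1-f) (w_{sat} - w_o) R_x}{u_o w_o + (g f/\alpha_k)\, w_o}}
#' with wall conductance `g = A~ D / r`. `f = 1` is the fixed
#' xylem-equilibrium wall, `f = 0` the Craig-Gordon wall (the `1/alpha_k`
#' terms cancel there because evaporation carries the supply composition),
#' and intermediate `f` the linear mixture of the two surface films, solved
#' jointly with the Craig-Gordon surface as a linear fixed point.
#'
#' @param surface A [surface_model()] object.
#' @param w_i,R_i Incoming mole fraction and named per-species ratio vector.
#' @param w_o Segment steady-state mole fraction (from
#'   [segment_vapor_steady_state()]).
#' @param xylem A [xylem_source()] object.
#' @param geom Segment geometry; `wetted_length_m` is the segment length.
#' @param flow,env Airflow and conditions.
#' @param alpha_k Kinetic fractionation (single value or named vector).
#' @return Named per-species vector of steady-state outflow ratios.
#' @export
segment_isotope_steady_state <- function(surface, w_i, R_i, w_o, xylem,
                                         geom, flow, env, alpha_k = NULL) {
  ak <- .alpha_k_vec(alpha_k)
  f <- surface$f
  w_sat <- saturation_mole_fraction(env$temperature_K, env$pressure_Pa)
  ap <- vapply(BOREQ_SPECIES, equilibrium_alpha, numeric(1), temperature_K = env$temperature_K)
  R_x <- xylem$ratio[BOREQ_SPECIES]
  R_i <- R_i[BOREQ_SPECIES]
  u <- .carrier_molar_flow(flow, env)
  g <- .wall_conductance(geom$wetted_length_m, env)
  num <- u * w_i * R_i + (g * f / ak) * w_sat * R_x / ap + g * (1 - f) * (w_sat - w_o) * R_x
  den <- u * w_o + (g * f / ak) * w_o
  if (any(den <= 0)) stop("degenerate segment: no flow and no wall exchange acting on the vapor")
  num / den
}

#' Dry-air inflow correction
#'
#' When the flow rate is measured on dry (or drier) air, the incoming molar
#' flow differs from the outgoing one by the water added in the borehole:
#' `u_i = u_o (1 - w_o) / (1 - w_i)`.
#'
#' @param u_o Outgoing molar (or volumetric) flow.
#' @param w_i,w_o Incoming and outgoing vapor mole fractions in `[0, 1)`.
#' @return Corrected incoming flow, in the units of `u_o`.
#' @export
dry_air_inflow_correction <- function(u_o, w_i, w_o) {
  if (any(w_i < 0 | w_i >= 1) || any(w_o < 0 | w_o >= 1))
    stop("mole fractions must lie in [0, 1)")
  u_o * (1 - w_o) / (1 - w_i)
}

#' Simulate vapor and isotope profiles along a borehole
#'
#' Discretizes the wetted borehole length into `N` equal segments along the
#' air flow path and chains the per-segment steady states: the outflow of
#' segment k is the inflow of segment k+1. Each segment applies
#' [segment_vapor_steady_state()] and [segment_isotope_steady_state()] under
#' the chosen wall closure. Large `N` approaches the continuous
#' advection-exchange solution; by default the outlet is compared against a
#' half-resolution run and a warning is raised if the two differ by more
#' than 0.01 per mil.
#'
#' @param geom,flow,env Geometry, airflow and conditions.
#' @param inflow A [vapor_parcel()]: the air entering the borehole. Must not
#'   be super-saturated.
#' @param xylem A [xylem_source()].
#' @param surface A [surface_model()]; default fixed xylem equilibrium.
#' @param N Number of segments (default 500).
#' @param alpha_k Kinetic fractionation (single value or named vector);
#'   package defaults if `NULL`.
#' @param check_convergence Compare against an `N/2` run (default TRUE).
#' @return A `boreq_sim` object: list with
#'   * `segments`: data.frame (`segment`, `position_m`, `w`, `h`,
#'     `d18O`, `d2H`) of per-segment outflow states,
#'   * `outlet`: a [vapor_parcel()] leaving the borehole,
#'   * `evaporation_total_mol_s`: net molar water flux added from the wall,
#'   * `mass_balance_residual`: relative closure error of the vapor budget,
#'   * `time_constants`: `t_d`, `t_u`, `t_w` (s),
#'   * the inputs (`geom`, `flow`, `env`, `surface`, `xylem`, `alpha_k`, `N`).
#' @examples
#' env <- env_conditions(283.15)
#' sim <- simulate_borehole(
#'   geom = borehole_geometry(0.005, wetted_length_m = 0.10),
#'   flow = airflow(ml_min_to_m3_s(40)),
#'   env = env,
#'   inflow = vapor_parcel(rh = 0.5, delta = c(O18 = -20, H2 = -150), env = env),
#'   xylem = xylem_source(c(O18 = -15, H2 = -120)))
#' sim$outlet$delta
#' @export
simulate_borehole <- function(geom, flow, env, inflow, xylem,
                              surface = surface_model("xylem_equilibrium"),
                              N = 500, alpha_k = NULL, check_convergence = TRUE) {
  stopifnot(inherits(geom, "boreq_geometry"), inherits(flow, "boreq_flow"),
            inherits(inflow, "boreq_parcel"), inherits(xylem, "boreq_xylem"),
            inherits(surface, "boreq_surface"))
  env <- .as_env(env)
  if (N < 1 || N != round(N)) stop("N must be a positive integer")
  ak <- .alpha_k_vec(alpha_k)
  w_sat <- saturation_mole_fraction(env$temperature_K, env$pressure_Pa)
  if (inflow$w > w_sat + 1e-12)
    stop("inflow is super-saturated at stem temperature: condensation regime, not modeled")

  chain <- .run_chain(geom, flow, env, inflow, xylem, surface, N, ak, w_sat)
  if (check_convergence && N >= 2) {
    half <- .run_chain(geom, flow, env, inflow, xylem, surface, ceiling(N / 2), ak, w_sat)
    dmax <- max(abs(ratio_to_delta(chain$R_out) - ratio_to_delta(half$R_out)))
    if (dmax > 0.01)
      warning(sprintf("segment grid not converged: outlet delta changes by %.3g per mil between N=%d and N=%d; increase N",
                      dmax, ceiling(N / 2), N))
  }

  u <- .carrier_molar_flow(flow, env)
  residual <- abs(u * chain$w[N] - (u * inflow$w + chain$evap_total)) /
    max(u * chain$w[N], .Machine$double.eps)
  outlet <- vapor_parcel(w = chain$w[N], delta = ratio_to_delta(chain$R_out))
  segments <- data.frame(
    segment = seq_len(N),
    position_m = geom$wetted_length_m * seq_len(N) / N,
    w = chain$w,
    h = chain$w / w_sat,
    d18O = ratio_to_delta(chain$R[, "O18"]),
    d2H = ratio_to_delta(chain$R[, "H2"])
  )
  structure(list(
    segments = segments,
    outlet = outlet,
    evaporation_total_mol_s = chain$evap_total,
    mass_balance_residual = residual,
    time_constants = list(t_d = diffusion_time(geom, env),
                          t_u = turnover_time(geom, flow),
                          t_w = vapor_time_constant(geom, flow, env)),
    geom = geom, flow = flow, env = env, surface = surface, xylem = xylem,
    alpha_k = ak, N = N
  ), class = "boreq_sim")
}

## Chain the per-segment closed forms; shared by simulate_borehole() and its
## convergence guard. Returns per-segment w, R matrix, outlet R, total
## evaporation (mol/s).
.run_chain <- function(geom, flow, env, inflow, xylem, surface, N, ak, w_sat) {
  seg_geom <- borehole_geometry(geom$radius_m,
                                wetted_length_m = geom$wetted_length_m / N)
  u <- .carrier_molar_flow(flow, env)
  g <- .wall_conductance(seg_geom$wetted_length_m, env)
  ap <- vapply(BOREQ_SPECIES, equilibrium_alpha, numeric(1), temperature_K = env$temperature_K)
  R_x <- xylem$ratio[BOREQ_SPECIES]
  f <- surface$f
  w <- numeric(N)
  R <- matrix(NA_real_, N, 2, dimnames = list(NULL, BOREQ_SPECIES))
  w_prev <- inflow$w
  R_prev <- inflow$ratio[BOREQ_SPECIES]
  evap <- 0
  wall_eq <- (g * f / ak) * w_sat * R_x / ap   # constant per-segment wall term
  for (k in seq_len(N)) {
    w_k <- (u * w_prev + g * w_sat) / (u + g)
    R_k <- (u * w_prev * R_prev + wall_eq + g * (1 - f) * (w_sat - w_k) * R_x) /
      (u * w_k + (g * f / ak) * w_k)
    evap <- evap + g * (w_sat - w_k)
    w[k] <- w_k
    R[k, ] <- R_k
    w_prev <- w_k
    R_prev <- R_k
  }
  list(w = w, R = R, R_out = R[N, ], evap_total = evap)
}

#' @export
print.boreq_sim <- function(x, ...) {
  cat("Borehole equilibration simulation\n")
  cat(sprintf("  geometry: r = %.1f mm, wetted length = %.3f m; N = %d segments\n",
              1000 * x$geom$radius_m, x$geom$wetted_length_m, x$N))
  cat(sprintf("  flow: %.1f mL/min (%s convention); T = %.2f K\n",
              x$flow$Q_m3_s * 6e7, x$flow$velocity_convention, x$env$temperature_K))
  cat(sprintf("  wall closure: %s (f = %.2f)\n", x$surface$case, x$surface$f))
  cat(sprintf("  time constants: t_d = %.3g s, t_u = %.3g s, t_w = %.3g s\n",
              x$time_constants$t_d, x$time_constants$t_u, x$time_constants$t_w))
  cat(sprintf("  outlet: h = %.3f, d18O = %.2f, d2H = %.2f per mil\n",
              x$segments$h[x$N], x$outlet$delta[["O18"]], x$outlet$delta[["H2"]]))
  invisible(x)
}
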