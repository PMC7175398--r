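## Parameter sweeps over the borehole simulation and the minimum-mixing
## search used to choose the mixed-closure fraction.

.SWEEP_VARS <- c("flow", "diameter", "inflow_rh", "mixing_fraction")
.SWEEP_CASES <- c("xylem_equilibrium", "craig_gordon", "mixed")

#' Sweep one parameter of the borehole simulation
#'
#' Runs [simulate_borehole()] over a grid of one driving variable and
#' returns outlet composition and humidity for each grid point and wall
#' closure. Solver errors (e.g. condensation) are caught and annotated per
#' row; the sweep continues.
#'
#' @param variable One of `"flow"` (grid in mL/min), `"diameter"` (stem
#'   diameter, m), `"inflow_rh"` (fraction of saturation at borehole
#'   conditions), `"mixing_fraction"` (f of the mixed closure).
#' @param grid Numeric vector of grid values, strictly monotone.
#' @param geom,flow,env,inflow,xylem Base configuration (see
#'   [simulate_borehole()]); the swept quantity is replaced per grid point.
#' @param cases Wall closures to evaluate (ignored for
#'   `"mixing_fraction"`, which always runs the mixed closure).
#' @param f_mixed Mixing fraction used by the `"mixed"` case (default 0.35).
#' @param N,alpha_k Passed to [simulate_borehole()].
#' @return A data.frame with columns `variable`, `value`, `case`, `f`,
#'   `outlet_d18O`, `outlet_d2H`, `outlet_h`, `error` (NA when the run
#'   succeeded). The attribute `"reference"` holds the two reference
#'   compositions per species: the liquid stem water and the vapor in
#'   equilibrium with it at `env` temperature.
#' @export
run_sweep <- function(variable, grid, geom, flow, env, inflow, xylem,
                      cases = c("xylem_equilibrium", "craig_gordon", "mixed"),
                      f_mixed = 0.35, N = 500, alpha_k = NULL) {
  variable <- match.arg(variable, .SWEEP_VARS)
  cases <- match.arg(cases, .SWEEP_CASES, several.ok = TRUE)
  if (!length(grid)) stop("grid must be non-empty")
  if (length(grid) > 1 && !(all(diff(grid) > 0) || all(diff(grid) < 0)))
    stop("grid must be strictly monotone")
  if (variable == "mixing_fraction") cases <- "mixed"

  rows <- list()
  for (value in grid) {
    for (case in cases) {
      f_use <- if (case == "mixed") f_mixed else NULL
      if (variable == "mixing_fraction") f_use <- value
      surf <- surface_model(case, f = f_use)
      res <- tryCatch({
        g <- geom; fl <- flow; iv <- inflow
        if (variable == "flow") fl <- airflow(ml_min_to_m3_s(value), flow$velocity_convention)
        if (variable == "diameter") g <- borehole_geometry(geom$radius_m, stem_diameter_m = value,
                                                           fitting_penetration_m = geom$fitting_penetration_m)
        if (variable == "inflow_rh") iv <- vapor_parcel(rh = value, delta = inflow$delta, env = env)
        simulate_borehole(g, fl, env, iv, xylem, surface = surf, N = N,
                          alpha_k = alpha_k, check_convergence = FALSE)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        rows[[length(rows) + 1L]] <- data.frame(
          variable = variable, value = value, case = case, f = surf$f,
          outlet_d18O = NA_real_, outlet_d2H = NA_real_, outlet_h = NA_real_,
          error = conditionMessage(res))
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          variable = variable, value = value, case = case, f = surf$f,
          outlet_d18O = res$outlet$delta[["O18"]],
          outlet_d2H = res$outlet$delta[["H2"]],
          outlet_h = res$segments$h[res$N],
          error = NA_character_)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  eq_vap <- vapply(BOREQ_SPECIES, function(sp)
    liquid_to_vapor_delta(xylem$delta[[sp]], sp, env$temperature_K), numeric(1))
  attr(out, "reference") <- list(liquid_stem_water = xylem$delta,
                                 equilibrium_vapor = eq_vap)
  out
}

#' Minimum mixing fraction that matches the xylem-equilibrium outlet
#'
#' Finds the smallest mixing fraction `f` of the mixed wall closure whose
#' outlet composition is within `tolerance` (per mil) of the
#' fixed-xylem-equilibrium outlet. Because the outlet delta is monotone in
#' `f` between the Craig-Gordon (`f = 0`) and xylem-equilibrium (`f = 1`)
#' values, the threshold is located by bisection.
#'
#' @param geom,flow,env,inflow,xylem Base configuration.
#' @param tolerance Per-mil tolerance defining "matches" (default 0.5).
#' @param species Species whose outlet delta is compared (default `"O18"`).
#' @param N,alpha_k Passed to [simulate_borehole()].
#' @param tol_f Resolution of the bisection in f (default 1e-4).
#' @return A list: `f` (the minimum fraction, 0 if even the pure
#'   Craig-Gordon outlet is within tolerance, NA if no `f <= 1` satisfies
#'   it), `tolerance`, `species`, `target_delta` (the xylem-equilibrium
#'   outlet), and `deviation_at_f`.
#' @export
find_min_mixing_fraction <- function(geom, flow, env, inflow, xylem,
                                     tolerance = 0.5, species = "O18",
                                     N = 500, alpha_k = NULL, tol_f = 1e-4) {
  if (tolerance <= 0) stop("tolerance must be positive")
  species <- .check_species(species)
  outlet_delta <- function(surf) {
    sim <- simulate_borehole(geom, flow, env, inflow, xylem, surface = surf,
                             N = N, alpha_k = alpha_k, check_convergence = FALSE)
    sim$outlet$delta[[species]]
  }
  target <- outlet_delta(surface_model("xylem_equilibrium"))
  dev_at <- function(f) abs(outlet_delta(surface_model("mixed", f = f)) - target)
  if (dev_at(0) <= tolerance)
    return(list(f = 0, tolerance = tolerance, species = species,
                target_delta = target, deviation_at_f = dev_at(0)))
  if (dev_at(1) > tolerance)
    return(list(f = NA_real_, tolerance = tolerance, species = species,
                target_delta = target, deviation_at_f = dev_at(1)))
  lo <- 0; hi <- 1
  while (hi - lo > tol_f) {
    mid <- (lo + hi) / 2
    if (dev_at(mid) <= tolerance) hi <- mid else lo <- mid
  }
  list(f = hi, tolerance = tolerance, species = species,
       target_delta = target, deviation_at_f = dev_at(hi))
}
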