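#' Borehole geometry
#'
#' Geometry of a cylindrical borehole drilled through a tree stem. The wetted
#' (exchanging) length defaults to the stem diameter minus the total length
#' blocked by the tubing fittings, which are screwed about 1 cm into either
#' side of the stem (2 cm total by default). Derived quantities are the air
#' volume `V = pi r^2 l` and the wetted wall area `A = 2 pi r l`; note
#' `A / r = 2 pi l` is independent of the radius, so widening the borehole
#' does not change the wall-exchange conductance per unit volume.
#'
#' @param radius_m Borehole radius (m).
#' @param stem_diameter_m Stem diameter (m). Required unless `wetted_length_m`
#'   is given explicitly.
#' @param fitting_penetration_m Total non-wetted length blocked by fittings
#'   (m); default 0.02.
#' @param wetted_length_m Optional explicit wetted length (m), overriding
#'   `stem_diameter_m - fitting_penetration_m`.
#' @return A `boreq_geometry` object: list with `radius_m`, `stem_diameter_m`,
#'   `fitting_penetration_m`, `wetted_length_m`, `volume_m3`, `wall_area_m2`.
#' @examples
#' borehole_geometry(radius_m = 0.005, stem_diameter_m = 0.099)
#' borehole_geometry(radius_m = 0.005, wetted_length_m = 0.10)
#' @export
borehole_geometry <- function(radius_m, stem_diameter_m = NULL,
                              fitting_penetration_m = 0.02,
                              wetted_length_m = NULL) {
  stopifnot(is.numeric(radius_m), length(radius_m) == 1L, radius_m > 0)
  if (is.null(wetted_length_m)) {
    if (is.null(stem_diameter_m))
      stop("supply either stem_diameter_m or wetted_length_m")
    stopifnot(stem_diameter_m > 0, fitting_penetration_m >= 0)
    wetted_length_m <- stem_diameter_m - fitting_penetration_m
  }
  if (wetted_length_m <= 0)
    stop("wetted length must be positive; check stem_diameter_m vs fitting_penetration_m")
  structure(list(
    radius_m = radius_m,
    stem_diameter_m = stem_diameter_m,
    fitting_penetration_m = fitting_penetration_m,
    wetted_length_m = wetted_length_m,
    volume_m3 = pi * radius_m^2 * wetted_length_m,
    wall_area_m2 = 2 * pi * radius_m * wetted_length_m
  ), class = "boreq_geometry")
}

#' Airflow through the borehole
#'
#' Volumetric flow pushed (or pulled) through the borehole, with the
#' convention linking the measured mean flow to the effective carrier flow.
#' For laminar flow the velocity profile is parabolic and the centerline
#' velocity is twice the mean, so the `"centerline_double"` convention takes
#' the effective carrier flow as twice the observed flow; `"mean"` uses the
#' observed flow unchanged.
#'
#' @param Q_m3_s Volumetric flow rate (m^3/s). See [ml_min_to_m3_s()] for
#'   the usual mL/min instrument units.
#' @param velocity_convention `"centerline_double"` (default) or `"mean"`.
#' @return A `boreq_flow` object.
#' @examples
#' airflow(ml_min_to_m3_s(80))
#' airflow(ml_min_to_m3_s(80), velocity_convention = "mean")
#' @export
airflow <- function(Q_m3_s, velocity_convention = c("centerline_double", "mean")) {
  stopifnot(is.numeric(Q_m3_s), length(Q_m3_s) == 1L)
  if (Q_m3_s <= 0) stop("flow rate must be positive")
  velocity_convention <- match.arg(velocity_convention)
  structure(list(Q_m3_s = Q_m3_s, velocity_convention = velocity_convention),
            class = "boreq_flow")
}

#' Convert mL/min to m^3/s
#'
#' @param ml_min Flow rate in milliliters per minute.
#' @return Flow rate in m^3/s.
#' @examples
#' ml_min_to_m3_s(80)  # 1.3333e-06
#' @export
ml_min_to_m3_s <- function(ml_min) ml_min * 1e-6 / 60

## Effective volumetric carrier flow under the chosen convention (m^3/s).
.carrier_flow <- function(flow) {
  mult <- if (flow$velocity_convention == "centerline_double") 2 else 1
  mult * flow$Q_m3_s
}

## Effective molar carrier flow u_o (mol/s).
.carrier_molar_flow <- function(flow, env) .carrier_flow(flow) / molar_volume(env)

#' An air parcel carrying water vapor and its isotopic composition
#'
#' Describes the moist air entering, inside, or leaving the borehole by its
#' water-vapor mole fraction and the per-species isotopic composition of
#' that vapor. The mole fraction may be given directly or via relative
#' humidity at given conditions.
#'
#' @param w Water-vapor mole fraction in `[0, 1)`. Give either `w` or `rh`.
#' @param rh Relative humidity in `[0, 1]`, converted to `w` via the
#'   saturation mole fraction at `env` conditions.
#' @param delta Named per-mil vector of the vapor composition, e.g.
#'   `c(O18 = -20, H2 = -150)`. Species not named default to 0 per mil
#'   (irrelevant for dry parcels).
#' @param env A [env_conditions()] object; required when `rh` is used.
#' @return A `boreq_parcel` object with fields `w` and `ratio` (named
#'   normalized ratios) and `delta` (named per-mil values).
#' @examples
#' env <- env_conditions(283.15)
#' vapor_parcel(rh = 0.5, delta = c(O18 = -20, H2 = -150), env = env)
#' @export
vapor_parcel <- function(w = NULL, rh = NULL, delta = c(O18 = 0, H2 = 0), env = NULL) {
  if (is.null(w) == is.null(rh)) stop("give exactly one of `w` or `rh`")
  if (!is.null(rh)) {
    if (rh < 0 || rh > 1) stop("rh must lie in [0, 1]")
    env <- .as_env(env)
    w <- rh * saturation_mole_fraction(env$temperature_K, env$pressure_Pa)
  }
  if (w < 0 || w >= 1) stop("mole fraction w must lie in [0, 1)")
  d <- c(O18 = 0, H2 = 0)
  if (length(delta)) {
    if (is.null(names(delta)) || !all(names(delta) %in% BOREQ_SPECIES))
      stop("`delta` must be a named vector with names in ", paste(BOREQ_SPECIES, collapse = ", "))
    d[names(delta)] <- delta
  }
  structure(list(w = w, delta = d, ratio = delta_to_ratio(d)),
            class = "boreq_parcel")
}

#' Liquid xylem water source composition
#'
#' The isotopic composition of the liquid water supplying the borehole wall,
#' i.e. the quantity the borehole method is designed to recover.
#'
#' @param delta Named per-mil vector, e.g. `c(O18 = -15, H2 = -120)`.
#' @return A `boreq_xylem` object with `delta` and normalized `ratio`.
#' @export
xylem_source <- function(delta = c(O18 = -15, H2 = -120)) {
  d <- c(O18 = 0, H2 = 0)
  if (is.null(names(delta)) || !all(names(delta) %in% BOREQ_SPECIES))
    stop("`delta` must be a named vector with names in ", paste(BOREQ_SPECIES, collapse = ", "))
  d[names(delta)] <- delta
  structure(list(delta = d, ratio = delta_to_ratio(d)), class = "boreq_xylem")
}

#' Surface-water closure for the borehole wall
#'
#' Chooses how the isotopic composition of the evaporating water film on the
#' borehole wall is closed:
#' * `"xylem_equilibrium"`: the film is pure xylem water, so the surface
#'   vapor is `R_x / alpha+` (the wall overwhelms the vapor signal);
#' * `"craig_gordon"`: the film has enriched to the Craig-Gordon steady
#'   state in which the evaporated flux carries the xylem composition;
#' * `"mixed"`: fraction `f` of the film is fresh xylem water and `1 - f`
#'   is at the Craig-Gordon steady state, i.e.
#'   `R_s = f R_x/alpha+ + (1 - f) R_C/alpha+`.
#'
#' @param case One of `"xylem_equilibrium"`, `"craig_gordon"`, `"mixed"`.
#' @param f Mixing fraction in `[0, 1]`, used by `"mixed"`; `f = 1`
#'   reproduces `"xylem_equilibrium"` exactly and `f = 0` reproduces
#'   `"craig_gordon"` exactly.
#' @return A `boreq_surface` object.
#' @export
surface_model <- function(case = c("xylem_equilibrium", "craig_gordon", "mixed"), f = NULL) {
  case <- match.arg(case)
  if (case == "mixed") {
    if (is.null(f)) stop("case \"mixed\" requires a mixing fraction `f`")
    stopifnot(is.numeric(f), length(f) == 1L)
    if (f < 0 || f > 1) stop("mixing fraction f must lie in [0, 1]")
  } else {
    f <- if (case == "xylem_equilibrium") 1 else 0
  }
  structure(list(case = case, f = f), class = "boreq_surface")
}
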