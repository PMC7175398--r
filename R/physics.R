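#' @keywords internal
"_PACKAGE"

## Physical constants used throughout the model.
.T0 <- 273.15      # standard temperature, K
.P0 <- 101325      # standard pressure, Pa
.D0 <- 2.12e-5     # diffusivity of water vapor in air at (T0, p0), m^2/s
.V0 <- 22.414e-3   # molar volume of an ideal gas at (T0, p0), m^3/mol

#' Heavy water isotopologues
#'
#' The two heavy isotopologues tracked by the package: `"O18"` (H2^18O,
#' reported as delta-18O) and `"H2"` (^1H^2H^16O, reported as delta-2H).
#' All per-species arguments and named vectors use these identifiers.
#'
#' @format Character vector of length 2.
#' @export
BOREQ_SPECIES <- c("O18", "H2")

.check_species <- function(species) {
  species <- match.arg(species, BOREQ_SPECIES, several.ok = FALSE)
  species
}

#' Environmental conditions of moist air
#'
#' Bundles absolute temperature and total pressure, the two state variables
#' every gas-phase law in the model depends on.
#'
#' @param temperature_K Absolute temperature (K). Must be positive.
#' @param pressure_Pa Total air pressure (Pa). Default 101325 Pa.
#' @return An object of class `boreq_env`: a list with elements
#'   `temperature_K` and `pressure_Pa`.
#' @examples
#' env_conditions(283.15)            # 10 degrees C at sea level
#' env_conditions(289.95, 101325)    # 16.8 degrees C
#' @export
env_conditions <- function(temperature_K, pressure_Pa = .P0) {
  stopifnot(is.numeric(temperature_K), length(temperature_K) == 1L,
            is.numeric(pressure_Pa), length(pressure_Pa) == 1L)
  if (temperature_K <= 0) stop("temperature_K must be positive (absolute temperature)")
  if (pressure_Pa <= 0) stop("pressure_Pa must be positive")
  structure(list(temperature_K = temperature_K, pressure_Pa = pressure_Pa),
            class = "boreq_env")
}

.as_env <- function(env) {
  if (inherits(env, "boreq_env")) return(env)
  stop("expected a `boreq_env` object created by env_conditions()")
}

#' Equilibrium liquid-vapor isotope fractionation factor
#'
#' Temperature-dependent equilibrium fractionation factor alpha+ (> 1) in the
#' liquid-over-vapor convention: vapor in equilibrium with liquid water has
#' ratio `R_vapor = R_liquid / alpha+`. Computed from the Majoube (1971)
#' polynomials in 1000 ln(alpha):
#' \deqn{10^3 \ln\alpha^+_{18O} = 1.137\,(10^6/T^2) - 0.4156\,(10^3/T) - 2.0667}
#' \deqn{10^3 \ln\alpha^+_{2H} = 24.844\,(10^6/T^2) - 76.248\,(10^3/T) + 52.612}
#'
#' @param species `"O18"` or `"H2"`.
#' @param temperature_K Absolute temperature (K); vectorized. A warning is
#'   issued outside 230-350 K, where the liquid-water polynomials are not
#'   intended to be used.
#' @return Dimensionless fractionation factor(s) alpha+ > 1.
#' @examples
#' equilibrium_alpha("O18", 293.15)  # about 1.0098
#' equilibrium_alpha("H2", 293.15)   # about 1.0850
#' @export
equilibrium_alpha <- function(species, temperature_K) {
  species <- .check_species(species)
  if (any(temperature_K <= 0)) stop("temperature_K must be positive")
  if (any(temperature_K < 230 | temperature_K > 350))
    warning("equilibrium_alpha: temperature outside 230-350 K; extrapolating the liquid-water polynomial")
  Ti <- temperature_K
  ln1000 <- if (species == "O18") {
    1.137 * (1e6 / Ti^2) - 0.4156 * (1e3 / Ti) - 2.0667
  } else {
    24.844 * (1e6 / Ti^2) - 76.248 * (1e3 / Ti) + 52.612
  }
  exp(ln1000 / 1000)
}

## Default kinetic fractionation factors: classical molecular-diffusivity
## ratios of the heavy isotopologues in air (Merlivat-type values).
.ALPHA_K_DEFAULT <- c(O18 = 1.0285, H2 = 1.0251)

#' Kinetic isotope fractionation factor for vapor diffusion
#'
#' Kinetic fractionation alpha_k (>= 1) acting on the diffusive exchange
#' between the wetted borehole wall and the laminar air stream. The defaults
#' are the classical molecular-diffusivity ratios in air: 1.0285 for
#' delta-18O and 1.0251 for delta-2H. Pass `override = 1` to disable kinetic
#' fractionation.
#'
#' @param species `"O18"` or `"H2"`.
#' @param override Optional dimensionless factor >= 1 replacing the default.
#' @return Dimensionless factor alpha_k >= 1.
#' @export
kinetic_alpha <- function(species, override = NULL) {
  species <- .check_species(species)
  if (is.null(override)) return(unname(.ALPHA_K_DEFAULT[species]))
  stopifnot(is.numeric(override), length(override) == 1L)
  if (override < 1) stop("kinetic alpha_k must be >= 1 (diffusion favors the light isotopologue)")
  override
}

#' Saturation vapor pressure over liquid water
#'
#' Murray (1967) formula for the saturation partial pressure of water vapor
#' over a plane liquid surface,
#' `e_sat = 610.78 * exp(17.2693882 * (T - 273.16) / (T - 35.86))` Pa,
#' anchored at 610.78 Pa at the triple point.
#'
#' @param temperature_K Absolute temperature (K); vectorized. Intended for
#'   T > 233 K (liquid water).
#' @return Saturation vapor pressure (Pa).
#' @examples
#' saturation_vapor_pressure(273.16)  # 610.78 Pa
#' saturation_vapor_pressure(283.15)  # about 1227 Pa
#' @export
saturation_vapor_pressure <- function(temperature_K) {
  if (any(temperature_K <= 35.86)) stop("temperature_K out of range for the liquid-water formula")
  if (any(temperature_K < 233)) warning("saturation_vapor_pressure: below 233 K the liquid-water formula is extrapolated")
  610.78 * exp(17.2693882 * (temperature_K - 273.16) / (temperature_K - 35.86))
}

#' Diffusivity of water vapor in air
#'
#' Power-law temperature and inverse pressure scaling
#' `D = D0 * (p0/p) * (T/T0)^1.88` with `D0 = 2.12e-5` m^2/s at standard
#' temperature and pressure.
#'
#' @param env A [env_conditions()] object.
#' @return Diffusivity (m^2/s).
#' @export
vapor_diffusivity <- function(env) {
  env <- .as_env(env)
  .D0 * (.P0 / env$pressure_Pa) * (env$temperature_K / .T0)^1.88
}

#' Molar volume of air
#'
#' Ideal-gas molar volume `V_1mol = 22.414e-3 * (T/T0) * (p0/p)` m^3/mol.
#'
#' @param env A [env_conditions()] object.
#' @return Molar volume (m^3/mol).
#' @export
molar_volume <- function(env) {
  env <- .as_env(env)
  .V0 * (env$temperature_K / .T0) * (.P0 / env$pressure_Pa)
}

#' Saturation water-vapor mole fraction at stem temperature
#'
#' `w_sat = e_sat(T_stem) / p`: the mole fraction the borehole air would hold
#' at saturation over the wetted wall.
#'
#' @param temperature_K Stem (wall) temperature (K); vectorized.
#' @param pressure_Pa Total pressure (Pa).
#' @return Mole fraction in (0, 1).
#' @export
saturation_mole_fraction <- function(temperature_K, pressure_Pa = .P0) {
  esat <- saturation_vapor_pressure(temperature_K)
  if (any(esat >= pressure_Pa))
    stop("saturation vapor pressure exceeds total pressure: boiling regime, not modeled")
  esat / pressure_Pa
}

#' Convert between delta notation and normalized isotope ratios
#'
#' Standard delta notation: `delta = (R/R_std - 1) * 1000` per mil relative to
#' VSMOW. Ratios are stored normalized to the standard (delta = 0 maps to
#' ratio 1), which is sufficient everywhere because the model equations are
#' homogeneous in R.
#'
#' @param delta Per-mil delta value(s); must exceed -1000.
#' @param ratio Normalized ratio(s); must be positive.
#' @return `delta_to_ratio` returns normalized ratios; `ratio_to_delta`
#'   returns per-mil deltas. Exact inverses of each other.
#' @examples
#' delta_to_ratio(0)        # 1
#' delta_to_ratio(1000)     # 2
#' ratio_to_delta(delta_to_ratio(-25.7))
#' @export
delta_to_ratio <- function(delta) {
  if (any(delta <= -1000)) stop("delta must be greater than -1000 per mil")
  1 + delta / 1000
}

#' @rdname delta_to_ratio
#' @export
ratio_to_delta <- function(ratio) {
  if (any(ratio <= 0)) stop("ratio must be positive")
  (ratio - 1) * 1000
}

#' Convert a vapor delta to its equilibrium liquid value (and back)
#'
#' Assuming liquid-vapor thermodynamic equilibrium at temperature T, the
#' liquid ratio is `R_liquid = alpha+(T) * R_vapor`. This is how calibrated
#' borehole vapor measurements are converted to liquid-equivalent xylem
#' water composition, and how liquid standards are converted to their
#' headspace vapor targets.
#'
#' @param delta_vapor,delta_liquid Per-mil delta value(s); vectorized.
#' @param species `"O18"` or `"H2"`.
#' @param temperature_K Equilibration temperature (K); vectorized
#'   (recycled against the deltas).
#' @return Per-mil delta of the other phase.
#' @examples
#' vapor_to_liquid_delta(-25.43, "O18", 283.15)  # about -15
#' @export
vapor_to_liquid_delta <- function(delta_vapor, species, temperature_K) {
  a <- equilibrium_alpha(species, temperature_K)
  ratio_to_delta(delta_to_ratio(delta_vapor) * a)
}

#' @rdname vapor_to_liquid_delta
#' @export
liquid_to_vapor_delta <- function(delta_liquid, species, temperature_K) {
  a <- equilibrium_alpha(species, temperature_K)
  ratio_to_delta(delta_to_ratio(delta_liquid) / a)
}
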