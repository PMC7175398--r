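## Configuration loading with unit normalization, plus the subcommand
## dispatcher behind the command-line entry point (inst/cli/boreq.R).

#' Parse a physical quantity with units to SI
#'
#' Accepts either a bare number (assumed already in the SI unit named by
#' `kind`) or a string `"<value> <unit>"`. Supported units: lengths
#' (`m`, `cm`, `mm`), flows (`m3/s`, `mL/min`, `L/min`), temperatures
#' (`K`, `C`), pressures (`Pa`, `kPa`, `hPa`), durations (`s`, `min`, `h`).
#'
#' @param x Number or string such as `"80 mL/min"`, `"16.8 C"`, `"5 mm"`.
#' @param kind One of `"length"`, `"flow"`, `"temperature"`, `"pressure"`,
#'   `"duration"`.
#' @return Value in SI units (m, m^3/s, K, Pa, s).
#' @examples
#' parse_quantity("80 mL/min", "flow")    # 1.3333e-06
#' parse_quantity("16.8 C", "temperature") # 289.95
#' @export
parse_quantity <- function(x, kind = c("length", "flow", "temperature", "pressure", "duration")) {
  kind <- match.arg(kind)
  if (is.numeric(x)) return(x)
  x <- trimws(x)
  m <- regmatches(x, regexec("^([-+0-9.eE]+)\\s*(.*)$", x))[[1L]]
  if (length(m) != 3L || is.na(suppressWarnings(as.numeric(m[2L]))))
    stop(sprintf("cannot parse quantity %s", dQuote(x)))
  value <- as.numeric(m[2L])
  unit <- m[3L]
  conv <- switch(kind,
    length = c(m = 1, cm = 1e-2, mm = 1e-3),
    flow = c("m3/s" = 1, "mL/min" = 1e-6 / 60, "ml/min" = 1e-6 / 60, "L/min" = 1e-3 / 60),
    pressure = c(Pa = 1, kPa = 1e3, hPa = 1e2),
    duration = c(s = 1, min = 60, h = 3600),
    temperature = NULL)
  if (kind == "temperature") {
    if (unit %in% c("K", "")) return(value)
    if (unit %in% c("C", "degC", "°C")) return(value + .T0)
    stop(sprintf("unknown temperature unit %s (expected K or C)", dQuote(unit)))
  }
  if (unit == "") return(value)
  if (!unit %in% names(conv))
    stop(sprintf("unknown %s unit %s (expected one of %s)", kind, dQuote(unit),
                 paste(names(conv), collapse = ", ")))
  value * conv[[unit]]
}

.MODEL_KEYS <- c("radius", "stem_diameter", "wetted_length", "fitting_penetration",
                 "flow", "velocity_convention", "temperature", "pressure",
                 "inflow_rh", "inflow_w", "inflow_d18o", "inflow_d2h",
                 "xylem_d18o", "xylem_d2h", "case", "f", "n_segments",
                 "alpha_k_o18", "alpha_k_h2")

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration with blocks `model` and optionally
#' `sweep`, `process`, `synth`. All physical quantities may carry units
#' (see [parse_quantity()]) and are normalized to SI on load. Unknown keys
#' are rejected by name.
#'
#' @param path Path to the configuration file.
#' @return A `boreq_config` list with a normalized `model` block and the
#'   raw remaining blocks.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$model)) stop("config must contain a `model` block")
  unknown <- setdiff(names(cfg$model), .MODEL_KEYS)
  if (length(unknown))
    stop("unknown key(s) in model block: ", paste(unknown, collapse = ", "),
         " (expected among: ", paste(.MODEL_KEYS, collapse = ", "), ")")
  m <- cfg$model
  norm <- list(
    radius_m = parse_quantity(m$radius %||% "5 mm", "length"),
    stem_diameter_m = if (!is.null(m$stem_diameter)) parse_quantity(m$stem_diameter, "length"),
    wetted_length_m = if (!is.null(m$wetted_length)) parse_quantity(m$wetted_length, "length"),
    fitting_penetration_m = parse_quantity(m$fitting_penetration %||% 0.02, "length"),
    Q_m3_s = parse_quantity(m$flow %||% "80 mL/min", "flow"),
    velocity_convention = m$velocity_convention %||% "centerline_double",
    temperature_K = parse_quantity(m$temperature %||% "16.8 C", "temperature"),
    pressure_Pa = parse_quantity(m$pressure %||% .P0, "pressure"),
    inflow_rh = m$inflow_rh,
    inflow_w = m$inflow_w,
    inflow_d18o = m$inflow_d18o %||% 0,
    inflow_d2h = m$inflow_d2h %||% 0,
    xylem_d18o = m$xylem_d18o %||% -15,
    xylem_d2h = m$xylem_d2h %||% -120,
    case = m$case %||% "xylem_equilibrium",
    f = m$f,
    n_segments = m$n_segments %||% 500,
    alpha_k = c(O18 = m$alpha_k_o18 %||% .ALPHA_K_DEFAULT[["O18"]],
                H2 = m$alpha_k_h2 %||% .ALPHA_K_DEFAULT[["H2"]])
  )
  if (is.null(norm$inflow_rh) && is.null(norm$inflow_w)) norm$inflow_rh <- 0
  structure(list(model = norm, sweep = cfg$sweep, process = cfg$process,
                 synth = cfg$synth, path = path),
            class = "boreq_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Build simulation inputs from a normalized model block.
.build_sim_args <- function(m) {
  env <- env_conditions(m$temperature_K, m$pressure_Pa)
  geom <- borehole_geometry(m$radius_m, stem_diameter_m = m$stem_diameter_m,
                            fitting_penetration_m = m$fitting_penetration_m,
                            wetted_length_m = m$wetted_length_m)
  flow <- airflow(m$Q_m3_s, m$velocity_convention)
  inflow <- if (!is.null(m$inflow_w)) {
    vapor_parcel(w = m$inflow_w, delta = c(O18 = m$inflow_d18o, H2 = m$inflow_d2h))
  } else {
    vapor_parcel(rh = m$inflow_rh, delta = c(O18 = m$inflow_d18o, H2 = m$inflow_d2h), env = env)
  }
  xylem <- xylem_source(c(O18 = m$xylem_d18o, H2 = m$xylem_d2h))
  surface <- surface_model(m$case, f = m$f)
  list(geom = geom, flow = flow, env = env, inflow = inflow, xylem = xylem,
       surface = surface, N = m$n_segments, alpha_k = m$alpha_k)
}

#' Run a boreq subcommand from a configuration
#'
#' Dispatches the four workflows behind the command-line entry point:
#' * `"simulate"`: one borehole run; writes the per-segment profile as CSV
#'   and a JSON summary (outlet composition, time constants);
#' * `"sweep"`: a parameter sweep (needs a `sweep` block with `variable`
#'   and `grid`); writes the sweep table as CSV;
#' * `"process"`: the measurement pipeline (needs a `process` block with
#'   `input` and `standards` paths); writes processed records CSV and a
#'   JSON run report;
#' * `"synth"`: a synthetic campaign (optional `synth` block overriding
#'   [campaign_config()] defaults); writes `raw.csv` and `truth.json`.
#'
#' Every JSON artifact embeds a provenance block (package version, config
#' path, seed, physical constants in use).
#'
#' @param subcommand One of `"simulate"`, `"sweep"`, `"process"`, `"synth"`.
#' @param config A [parse_config()] object or a path to a config file.
#' @param out Output file or directory path (directory for `"synth"`).
#' @param seed Integer seed for `"synth"`.
#' @return Invisibly, the computed object.
#' @export
run_boreq <- function(subcommand = c("simulate", "sweep", "process", "synth"),
                      config, out, seed = 1L) {
  subcommand <- match.arg(subcommand)
  if (is.character(config)) config <- parse_config(config)
  stopifnot(inherits(config, "boreq_config"))
  prov <- list(package = "boreq",
               version = as.character(utils::packageVersion("boreq")),
               config = config$path, seed = seed,
               constants = list(T0_K = .T0, p0_Pa = .P0, D0_m2_s = .D0,
                                V0_m3_mol = .V0, alpha_k_default = as.list(.ALPHA_K_DEFAULT)))
  if (subcommand == "simulate") {
    a <- .build_sim_args(config$model)
    sim <- simulate_borehole(a$geom, a$flow, a$env, a$inflow, a$xylem,
                             surface = a$surface, N = a$N, alpha_k = a$alpha_k)
    utils::write.csv(sim$segments, out, row.names = FALSE)
    summary_path <- sub("\\.csv$", "_summary.json", out)
    jsonlite::write_json(list(
      outlet = list(w = sim$outlet$w, h = sim$segments$h[sim$N],
                    d18O = sim$outlet$delta[["O18"]], d2H = sim$outlet$delta[["H2"]]),
      time_constants = sim$time_constants,
      evaporation_total_mol_s = sim$evaporation_total_mol_s,
      mass_balance_residual = sim$mass_balance_residual,
      provenance = prov), summary_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(sim))
  }
  if (subcommand == "sweep") {
    sw <- config$sweep
    if (is.null(sw$variable) || is.null(sw$grid))
      stop("sweep requires `sweep: {variable, grid}` in the config")
    a <- .build_sim_args(config$model)
    tab <- run_sweep(sw$variable, unlist(sw$grid), a$geom, a$flow, a$env,
                     a$inflow, a$xylem,
                     cases = unlist(sw$cases %||% .SWEEP_CASES),
                     f_mixed = sw$f_mixed %||% 0.35, N = a$N, alpha_k = a$alpha_k)
    utils::write.csv(tab, out, row.names = FALSE)
    return(invisible(tab))
  }
  if (subcommand == "process") {
    pc <- config$process
    if (is.null(pc$input) || is.null(pc$standards))
      stop("process requires `process: {input, standards}` paths in the config")
    res <- process_campaign(pc$input, pc$standards,
                            window_s = parse_quantity(pc$window %||% 180, "duration"),
                            sd_limit_o18 = pc$sd_limit_o18 %||% 0.5,
                            sd_limit_h2 = pc$sd_limit_h2 %||% 1.5,
                            rh_min = pc$rh_min %||% 0.8)
    recs <- res$records
    recs$cycle_start <- format(recs$cycle_start, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    recs$cycle_end <- format(recs$cycle_end, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    utils::write.csv(recs, out, row.names = FALSE)
    report_path <- sub("\\.csv$", "_report.json", out)
    jsonlite::write_json(c(res$report, list(provenance = prov)), report_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(res))
  }
  # synth
  sy <- config$synth %||% list()
  sy <- lapply(sy, function(x) if (is.list(x)) unlist(x) else x)
  if (!is.null(sy$start)) sy$start <- as.POSIXct(sy$start, tz = "UTC")
  known <- names(formals(campaign_config))
  unknown <- setdiff(names(sy), known)
  if (length(unknown)) stop("unknown key(s) in synth block: ", paste(unknown, collapse = ", "))
  cc <- do.call(campaign_config, sy)
  campaign <- generate_campaign(cc, seed = seed)
  write_campaign(campaign, out)
  invisible(campaign)
}
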