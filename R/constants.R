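#' Physical constants for black-body radiometry
#'
#' Bundle of the physical constants driving every Planck-law computation in
#' the package. Defaults are the rounded values conventional in photobiology
#' calculations (`h` = 6.626e-34 J s, `c` = 2.998e8 m s^-1,
#' `k_B` = 1.381e-23 J K^-1), together with the solar geometry
#' (`R_sun` = 6.95e8 m, `R_orbit` = 1.50e11 m) and the effective black-body
#' temperature of the sun (5778 K). Keeping the rounded values as defaults,
#' rather than full-precision CODATA, makes the package reproduce the
#' irradiance tables these constants were originally used to compute; any
#' constant can be overridden.
#'
#' @param planck_h Planck's constant, J s.
#' @param light_speed_c Speed of light in vacuum, m s^-1.
#' @param boltzmann_kB Boltzmann's constant, J K^-1.
#' @param sun_radius Radius of the sun, m.
#' @param orbit_radius Mean radius of the earth's orbit, m.
#' @param sun_temperature Effective black-body temperature of the sun, K.
#'
#' @return An object of class `physical_constants`: a named list of the six
#'   strictly positive constants.
#' @examples
#' pc <- physical_constants()
#' pc$planck_h
#' # override the solar temperature only
#' physical_constants(sun_temperature = 5772)
#' @export
physical_constants <- function(planck_h = 6.626e-34,
                               light_speed_c = 2.998e8,
                               boltzmann_kB = 1.381e-23,
                               sun_radius = 6.95e8,
                               orbit_radius = 1.50e11,
                               sun_temperature = 5778) {
  pc <- list(
    planck_h = planck_h,
    light_speed_c = light_speed_c,
    boltzmann_kB = boltzmann_kB,
    sun_radius = sun_radius,
    orbit_radius = orbit_radius,
    sun_temperature = sun_temperature
  )
  for (nm in names(pc)) {
    v <- pc[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("physical constant '", nm, "' must be a single finite positive number",
           call. = FALSE)
    }
  }
  structure(pc, class = "physical_constants")
}

#' @export
print.physical_constants <- function(x, ...) {
  cat("Physical constants:\n")
  cat(sprintf("  %-16s %g\n", names(x), unlist(x)), sep = "")
  invisible(x)
}

#' Read physical constants from a YAML or JSON config file
#'
#' Reads a config file holding any subset of the six constants (keys as in
#' [physical_constants()], optionally nested under a `constants` block).
#' Absent keys fall back to the package defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `physical_constants` object.
#' @export
read_constants <- function(path) {
  if (!file.exists(path)) stop("constants file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  constants_from_list(cfg)
}

#' Build constants from a plain list, filling in defaults
#'
#' @param cfg A named list; may contain a `constants` sub-list. Unknown keys
#'   are rejected to catch typos.
#' @return A `physical_constants` object.
#' @export
constants_from_list <- function(cfg) {
  if (!is.null(cfg$constants)) cfg <- cfg$constants
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  known <- names(formals(physical_constants))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stop("unknown constant name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(physical_constants, cfg)
}

#' Temperature conversions
#'
#' Celsius to Kelvin conversion is exact: K = degC + 273.15. `as_kelvin()`
#' validates that an absolute temperature is strictly positive.
#'
#' @param celsius Temperature(s) in degrees Celsius.
#' @return Temperature(s) in Kelvin.
#' @examples
#' celsius_to_kelvin(22)  # 295.15
#' @export
celsius_to_kelvin <- function(celsius) {
  stopifnot(is.numeric(celsius))
  k <- celsius + 273.15
  as_kelvin(k)
}

#' @rdname celsius_to_kelvin
#' @param kelvin Temperature(s) in Kelvin; must be strictly positive.
#' @export
as_kelvin <- function(kelvin) {
  if (!is.numeric(kelvin) || any(!is.finite(kelvin)) || any(kelvin <= 0)) {
    stop("absolute temperature must be finite and > 0 K", call. = FALSE)
  }
  kelvin
}

# Growth-chamber temperatures used throughout (degC); the reference is 22 degC.
#' Default plant-physiological growth temperatures
#'
#' The six growth temperatures (degrees Celsius) used across the spectral and
#' hypocotyl analyses, spanning the physiologically relevant 4-37 degC range,
#' with 22 degC serving as the reference condition.
#'
#' @return Numeric vector `c(4, 12, 16, 22, 28, 37)`.
#' @export
default_temperatures_c <- function() c(4, 12, 16, 22, 28, 37)

#' @rdname default_temperatures_c
#' @export
reference_temperature_c <- function() 22
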