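#' Planck spectral energy density
#'
#' Spectral energy density of black-body radiation,
#' \deqn{\rho_T(\lambda) = \frac{8\pi h c}{\lambda^5}\,
#'   \frac{1}{e^{hc/\lambda k_B T} - 1},}
#' in J m^-4 (energy per unit volume per unit wavelength). Vectorized over
#' `wavelength` and `temperature` (recycled).
#'
#' @param wavelength Wavelength(s) in metres; strictly positive.
#' @param temperature Absolute temperature(s) in Kelvin; strictly positive.
#' @param constants A [physical_constants()] object.
#' @return Spectral energy density, J m^-4.
#' @examples
#' spectral_energy_density(10e-6, celsius_to_kelvin(22))
#' @export
spectral_energy_density <- function(wavelength, temperature,
                                    constants = physical_constants()) {
  check_wavelength(wavelength)
  temperature <- as_kelvin(temperature)
  h <- constants$planck_h
  cc <- constants$light_speed_c
  kB <- constants$boltzmann_kB
  8 * pi * h * cc / wavelength^5 / expm1(h * cc / (wavelength * kB * temperature))
}

#' Planck spectral plane irradiance
#'
#' Spectral plane irradiance of a black body,
#' \deqn{E_{dT}(\lambda) = \frac{2\pi h c^2}{\lambda^5}\,
#'   \frac{1}{e^{hc/\lambda k_B T} - 1},}
#' reported per nanometre of wavelength (W m^-2 nm^-1). The plane irradiance
#' follows from the energy density via E = c * rho and, for isotropic
#' radiation, E_d = E / 4.
#'
#' @inheritParams spectral_energy_density
#' @param per Output wavelength unit: `"nm"` (default, W m^-2 nm^-1) or
#'   `"m"` (W m^-3).
#' @return Spectral plane irradiance.
#' @examples
#' # thermal IR emission of a 22 degC environment at 10 um
#' spectral_plane_irradiance(10e-6, celsius_to_kelvin(22))
#' @export
spectral_plane_irradiance <- function(wavelength, temperature,
                                      constants = physical_constants(),
                                      per = c("nm", "m")) {
  per <- match.arg(per)
  e_per_m <- constants$light_speed_c / 4 *
    spectral_energy_density(wavelength, temperature, constants)
  if (per == "nm") e_per_m * 1e-9 else e_per_m
}

#' Solar spectral irradiance at the earth's orbit
#'
#' Black-body spectral irradiance of the sun diluted by the inverse-square
#' distance factor,
#' \deqn{E_{d,\mathrm{solar}}(\lambda) =
#'   \left(R_\mathrm{sun}/R_\mathrm{orbit}\right)^2 E_{dT_\mathrm{sun}}(\lambda).}
#'
#' @inheritParams spectral_plane_irradiance
#' @return Solar spectral irradiance, W m^-2 nm^-1 (or W m^-3 with
#'   `per = "m"`).
#' @examples
#' solar_spectral_irradiance(660e-9)  # red light, ~1.5 W m^-2 nm^-1
#' @export
solar_spectral_irradiance <- function(wavelength,
                                      constants = physical_constants(),
                                      per = c("nm", "m")) {
  (constants$sun_radius / constants$orbit_radius)^2 *
    spectral_plane_irradiance(wavelength, constants$sun_temperature,
                              constants, per = match.arg(per))
}

#' Wien peak wavelength of the Planck spectrum
#'
#' Wavelength maximizing the per-wavelength Planck irradiance at a given
#' temperature. The maximum satisfies \eqn{\lambda_{max} T = hc / (x^* k_B)}
#' where \eqn{x^*} is the root of \eqn{x e^x / (e^x - 1) = 5}; the root is
#' found by bracketed root-finding to 1e-10 (a grid argmax is kept as an
#' independent oracle in the test suite).
#'
#' @inheritParams spectral_energy_density
#' @return Peak wavelength(s) in metres.
#' @examples
#' peak_wavelength(5778) * 1e9       # ~501 nm (solar)
#' peak_wavelength(295.15) * 1e6     # ~9.8 um (ambient 22 degC)
#' @export
peak_wavelength <- function(temperature, constants = physical_constants()) {
  temperature <- as_kelvin(temperature)
  x_star <- wien_root()
  constants$planck_h * constants$light_speed_c /
    (x_star * constants$boltzmann_kB * temperature)
}

# Root of x * e^x / (e^x - 1) = 5 (dimensionless Wien equation).
# Cached: the root does not depend on the constants.
wien_root <- local({
  root <- NULL
  function() {
    if (is.null(root)) {
      f <- function(x) x / (1 - exp(-x)) - 5
      root <<- stats::uniroot(f, c(1, 10), tol = 1e-12)$root
    }
    root
  }
})

#' Band-integrated plane irradiance (Stefan-Boltzmann check)
#'
#' Numerically integrates the spectral plane irradiance over a wavelength
#' band by adaptive quadrature (relative tolerance 1e-10). Over the default
#' band (10 nm to 1 mm) the integral recovers the Stefan-Boltzmann total
#' \eqn{\sigma T^4}, \eqn{\sigma = 2\pi^5 k_B^4 / 15 h^3 c^2}, to well within
#' 0.1%.
#'
#' @inheritParams spectral_energy_density
#' @param lambda_lo,lambda_hi Band edges in metres, `0 < lambda_lo < lambda_hi`.
#' @return Band irradiance, W m^-2.
#' @seealso [stefan_boltzmann_total()] for the closed form.
#' @examples
#' total_irradiance(celsius_to_kelvin(22))          # ~430.7 W m^-2
#' stefan_boltzmann_total(celsius_to_kelvin(22))
#' @export
total_irradiance <- function(temperature, constants = physical_constants(),
                             lambda_lo = 10e-9, lambda_hi = 1e-3) {
  temperature <- as_kelvin(temperature)
  stopifnot(length(temperature) == 1L)
  if (!is.numeric(lambda_lo) || !is.numeric(lambda_hi) ||
      lambda_lo <= 0 || lambda_hi <= lambda_lo) {
    stop("need 0 < lambda_lo < lambda_hi", call. = FALSE)
  }
  stats::integrate(
    function(l) spectral_plane_irradiance(l, temperature, constants, per = "m"),
    lower = lambda_lo, upper = lambda_hi,
    rel.tol = 1e-10, subdivisions = 2000L
  )$value
}

#' @rdname total_irradiance
#' @export
stefan_boltzmann_constant <- function(constants = physical_constants()) {
  2 * pi^5 * constants$boltzmann_kB^4 /
    (15 * constants$planck_h^3 * constants$light_speed_c^2)
}

#' @rdname total_irradiance
#' @export
stefan_boltzmann_total <- function(temperature, constants = physical_constants()) {
  stefan_boltzmann_constant(constants) * as_kelvin(temperature)^4
}

#' Photon flux from spectral irradiance
#'
#' Converts a monochromatic spectral irradiance into a photon flux by
#' dividing by the photon energy \eqn{hc/\lambda}:
#' \eqn{N_\lambda = E \lambda / (hc)}, in photons m^-2 s^-1 nm^-1. The flux is
#' monochromatic at the nominal wavelength (not band-integrated), as the
#' kinetics model requires.
#'
#' @param irradiance Spectral irradiance, W m^-2 nm^-1; non-negative.
#' @inheritParams spectral_energy_density
#' @return Photon flux, photons m^-2 s^-1 nm^-1.
#' @export
photon_flux <- function(irradiance, wavelength, constants = physical_constants()) {
  if (!is.numeric(irradiance) || any(irradiance < 0)) {
    stop("irradiance must be non-negative", call. = FALSE)
  }
  check_wavelength(wavelength)
  irradiance * wavelength / (constants$planck_h * constants$light_speed_c)
}

#' Thermal IR photon flux of an environment
#'
#' Photon flux of environmental thermal radiation at the nominal IR
#' wavelength (10 um by default, the peak region of ambient-temperature
#' black-body emission).
#'
#' @inheritParams spectral_energy_density
#' @param wavelength Nominal IR wavelength, m.
#' @return Photon flux N_IR, photons m^-2 s^-1 nm^-1.
#' @export
ir_photon_flux <- function(temperature, constants = physical_constants(),
                           wavelength = 10e-6) {
  photon_flux(
    spectral_plane_irradiance(wavelength, temperature, constants),
    wavelength, constants
  )
}

#' Relative R:IR ratio between two temperatures
#'
#' Under constant visible illumination the red photon flux N_R is fixed while
#' the thermal IR flux N_IR tracks temperature, so the R:IR ratio at
#' temperature T2 relative to a reference T1 reduces to
#' \deqn{r(T_1, T_2) = \frac{N_R / N_{IR}(T_2)}{N_R / N_{IR}(T_1)}
#'   = \frac{N_{IR}(T_1)}{N_{IR}(T_2)},}
#' with N_IR evaluated at 10 um. Warmer environments emit more IR, so
#' `r < 1` for `temp_query` above the reference.
#'
#' @param temp_ref Reference absolute temperature, K (typically 295.15 K).
#' @param temp_query Query absolute temperature, K.
#' @inheritParams spectral_energy_density
#' @param wavelength Nominal IR wavelength, m.
#' @return Dimensionless relative R:IR ratio; 1 when `temp_query == temp_ref`.
#' @examples
#' relative_r_ir_ratio(celsius_to_kelvin(22), celsius_to_kelvin(37))  # ~0.79
#' @export
relative_r_ir_ratio <- function(temp_ref, temp_query,
                                constants = physical_constants(),
                                wavelength = 10e-6) {
  ir_photon_flux(temp_ref, constants, wavelength) /
    ir_photon_flux(temp_query, constants, wavelength)
}

#' Build a black-body spectrum on a wavelength grid
#'
#' Evaluates spectral plane irradiance (or its solar-diluted counterpart) on
#' a strictly increasing wavelength grid and returns a `spectrum` data frame.
#'
#' @param temperature Absolute temperature, K. Ignored for `source = "solar"`
#'   (the solar temperature in `constants` is used).
#' @param wavelengths Strictly increasing wavelength grid, m. Default: 4000
#'   log-spaced points from 10 nm to 1 mm.
#' @inheritParams spectral_energy_density
#' @param source `"environment"` (undiluted black body at `temperature`) or
#'   `"solar"` (diluted by the orbit geometry).
#' @return A data frame of class `spectrum` with columns `wavelength_nm`,
#'   `irradiance_W_m2_nm`, `temperature_K`, `source`.
#' @examples
#' sp <- blackbody_spectrum(celsius_to_kelvin(22))
#' head(sp)
#' @export
blackbody_spectrum <- function(temperature = NULL,
                               wavelengths = default_wavelength_grid(),
                               constants = physical_constants(),
                               source = c("environment", "solar")) {
  source <- match.arg(source)
  check_wavelength(wavelengths)
  if (is.unsorted(wavelengths, strictly = TRUE)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (source == "solar") {
    temperature <- constants$sun_temperature
    irr <- solar_spectral_irradiance(wavelengths, constants)
  } else {
    temperature <- as_kelvin(temperature)
    stopifnot(length(temperature) == 1L)
    irr <- spectral_plane_irradiance(wavelengths, temperature, constants)
  }
  structure(
    data.frame(
      wavelength_nm = wavelengths * 1e9,
      irradiance_W_m2_nm = irr,
      temperature_K = temperature,
      source = source
    ),
    class = c("spectrum", "data.frame")
  )
}

#' @rdname blackbody_spectrum
#' @param n Number of grid points.
#' @param lambda_lo,lambda_hi Grid limits, m.
#' @export
default_wavelength_grid <- function(n = 4000L, lambda_lo = 10e-9,
                                    lambda_hi = 1e-3) {
  exp(seq(log(lambda_lo), log(lambda_hi), length.out = n))
}

#' Write a spectrum to CSV
#'
#' Writes the four spectrum columns in wavelength order; output is
#' deterministic so repeated runs are byte-identical.
#'
#' @param spectrum A `spectrum` data frame from [blackbody_spectrum()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "spectrum"))
  sp <- spectrum[order(spectrum$wavelength_nm), , drop = FALSE]
  utils::write.csv(sp, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

check_wavelength <- function(wavelength) {
  if (!is.numeric(wavelength) || any(!is.finite(wavelength)) ||
      any(wavelength <= 0)) {
    stop("wavelength must be finite and > 0 m", call. = FALSE)
  }
  invisible(wavelength)
}
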