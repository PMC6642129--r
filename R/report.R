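#' Run configuration for report generation
#'
#' Collects everything a report command needs: the physical constants,
#' growth temperatures, the physiological wavelengths of the irradiance
#' table, an output directory and a seed. All defaults are embedded, so every
#' report runs with no arguments.
#'
#' @param constants A [physical_constants()] object or a named list of
#'   overrides.
#' @param temperatures_c Growth temperatures, degC.
#' @param wavelengths Physiological wavelengths, m. Defaults: 310 nm (UV-B),
#'   470 nm (blue), 660 nm (red), 730 nm (far-red), 10 um (IR).
#' @param out_dir Output directory; created if missing.
#' @param seed Integer seed for any stochastic step.
#' @param archetypes Archetypes used by [report_synthfit()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(constants = physical_constants(),
                       temperatures_c = default_temperatures_c(),
                       wavelengths = default_band_wavelengths(),
                       out_dir = ".",
                       seed = 1L,
                       archetypes = builtin_archetypes()) {
  if (!inherits(constants, "physical_constants")) {
    constants <- constants_from_list(constants)
  }
  stopifnot(is.numeric(temperatures_c), length(temperatures_c) >= 1L,
            is.numeric(wavelengths), all(wavelengths > 0))
  structure(
    list(constants = constants, temperatures_c = temperatures_c,
         wavelengths = wavelengths, out_dir = out_dir,
         seed = as.integer(seed), archetypes = archetypes),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path YAML or JSON config file; recognized keys `constants`,
#'   `temperatures_c`, `wavelengths_nm`, `out_dir`, `seed`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- list()
  if (!is.null(cfg$constants)) args$constants <- constants_from_list(cfg$constants)
  if (!is.null(cfg$temperatures_c)) args$temperatures_c <- cfg$temperatures_c
  if (!is.null(cfg$wavelengths_nm)) args$wavelengths <- cfg$wavelengths_nm * 1e-9
  if (!is.null(cfg$out_dir)) args$out_dir <- cfg$out_dir
  if (!is.null(cfg$seed)) args$seed <- cfg$seed
  do.call(run_config, args)
}

#' @rdname run_config
#' @export
default_band_wavelengths <- function() {
  c(UVB = 310e-9, B = 470e-9, R = 660e-9, FR = 730e-9, IR = 10e-6)
}

# Reference irradiance values (W m^-2 nm^-1) against which the table is
# checked, with relative tolerances. Only the thermal IR row and four solar
# cells are registered: the visible-range thermal entries of the published
# table are internally inconsistent with the stated Planck formula (a
# consistent ~1.6x factor) and are deliberately left unverified.
golden_table1 <- function() {
  data.frame(
    wavelength_nm = c(rep(10000, 6), 310, 470, 660, 10000),
    column = c("4", "12", "16", "22", "28", "37", rep("solar", 4)),
    value = c(0.0210, 0.0243, 0.0260, 0.0288, 0.0318, 0.0366,
              0.91, 1.77, 1.52, 2.86e-4),
    rel_tol = c(rep(0.01, 6), rep(0.015, 4))
  )
}

#' Irradiance table at the physiological wavelengths
#'
#' Computes the solar and environmental-thermal spectral irradiance matrix
#' (wavelengths x (solar + temperatures)), writes it as CSV, and writes a
#' JSON check report comparing each cell against its registered reference
#' value where one exists (the thermal IR row and the verified solar cells);
#' other cells are flagged `"unverified"`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the table (`table`), the per-cell checks
#'   (`checks`) and the output paths. The check status is `"pass"`,
#'   `"fail"` or `"unverified"`.
#' @export
report_table1 <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  pc <- config$constants
  wl <- config$wavelengths
  tab <- data.frame(wavelength_nm = wl * 1e9,
                    solar = solar_spectral_irradiance(wl, pc))
  for (tc in config$temperatures_c) {
    tab[[as.character(tc)]] <-
      spectral_plane_irradiance(wl, celsius_to_kelvin(tc), pc)
  }
  golden <- golden_table1()
  checks <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    cols <- setdiff(names(tab), "wavelength_nm")
    do.call(rbind, lapply(cols, function(col) {
      g <- golden[golden$wavelength_nm == tab$wavelength_nm[i] &
                    golden$column == col, ]
      val <- tab[[col]][i]
      if (nrow(g) == 1L) {
        dev <- abs(val / g$value - 1)
        data.frame(wavelength_nm = tab$wavelength_nm[i], column = col,
                   value = val, reference = g$value, rel_deviation = dev,
                   status = if (dev <= g$rel_tol) "pass" else "fail")
      } else {
        data.frame(wavelength_nm = tab$wavelength_nm[i], column = col,
                   value = val, reference = NA_real_,
                   rel_deviation = NA_real_, status = "unverified")
      }
    }))
  }))
  csv_path <- file.path(config$out_dir, "table1.csv")
  json_path <- file.path(config$out_dir, "table1_checks.json")
  utils::write.csv(tab, csv_path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(checks, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(list(table = tab, checks = checks,
                 paths = c(csv = csv_path, json = json_path)))
}

#' Full spectra and peak summary
#'
#' Writes one spectrum CSV per source (solar plus each environmental
#' temperature) over the default wavelength grid, and a peak summary CSV
#' holding each source's Wien peak wavelength and maximal spectral
#' irradiance.
#'
#' @param config A [run_config()].
#' @param n_grid Number of grid points per spectrum.
#' @return Invisibly, a list with the peak summary data frame and the paths
#'   written.
#' @export
report_spectra <- function(config = run_config(), n_grid = 2000L) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  pc <- config$constants
  grid <- default_wavelength_grid(n = n_grid)
  paths <- character(0)

  sp_solar <- blackbody_spectrum(wavelengths = grid, constants = pc,
                                 source = "solar")
  p <- file.path(config$out_dir, "spectrum_solar.csv")
  write_spectrum_csv(sp_solar, p)
  paths <- c(paths, p)

  peaks <- data.frame(
    source = "solar",
    temperature_K = pc$sun_temperature,
    peak_wavelength_nm = peak_wavelength(pc$sun_temperature, pc) * 1e9,
    peak_irradiance_W_m2_nm =
      solar_spectral_irradiance(peak_wavelength(pc$sun_temperature, pc), pc)
  )
  for (tc in config$temperatures_c) {
    tk <- celsius_to_kelvin(tc)
    sp <- blackbody_spectrum(tk, grid, pc)
    p <- file.path(config$out_dir, sprintf("spectrum_%gC.csv", tc))
    write_spectrum_csv(sp, p)
    paths <- c(paths, p)
    lam <- peak_wavelength(tk, pc)
    peaks <- rbind(peaks, data.frame(
      source = sprintf("%g C", tc), temperature_K = tk,
      peak_wavelength_nm = lam * 1e9,
      peak_irradiance_W_m2_nm = spectral_plane_irradiance(lam, tk, pc)
    ))
  }
  peak_path <- file.path(config$out_dir, "peaks.csv")
  utils::write.csv(peaks, peak_path, row.names = FALSE, quote = FALSE)
  invisible(list(peaks = peaks, paths = c(paths, peak_path)))
}

#' Relative half-life series and regression report
#'
#' Computes the relative Pfr dark-reversion half-life at each configured
#' temperature, the log2 series, and the half-life-vs-temperature regression,
#' and writes them as JSON.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the series data frame, the
#'   `regression_result` and the JSON path.
#' @export
report_halflife <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- half_life_regression(config$temperatures_c, config$constants)
  series <- attr(res, "series")
  out <- list(
    series = series,
    regression = list(slope = res$slope, intercept = res$intercept,
                      r_squared = res$r_squared, n = res$n),
    constants = unclass(config$constants)
  )
  path <- file.path(config$out_dir, "halflife.json")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(list(series = series, regression = res, path = path))
}

#' End-to-end synthetic generation and fitting report
#'
#' Generates one seeded synthetic hypocotyl dataset per configured archetype,
#' fits each with [hypocotyl_response_fit()], ranks genotype sensitivities,
#' and writes dataset CSVs plus a JSON fit report.
#'
#' @param config A [run_config()].
#' @param n_per_temp Seedlings per temperature.
#' @return Invisibly, a list with the per-genotype fits, the sensitivity
#'   ranking and the paths written.
#' @export
report_synthfit <- function(config = run_config(), n_per_temp = 15L) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  fits <- list()
  paths <- character(0)
  for (arch in config$archetypes) {
    ds <- generate_hypocotyl_data(arch, config$temperatures_c, n_per_temp,
                                  seed = config$seed,
                                  constants = config$constants)
    p <- file.path(config$out_dir, sprintf("synthetic_%s.csv", arch$name))
    write_hypocotyl_csv(ds, p)
    paths <- c(paths, p)
    fits[[arch$name]] <- hypocotyl_response_fit(ds)[[arch$name]]
  }
  ranking <- sensitivity_comparison(fits)
  json_path <- file.path(config$out_dir, "synthfit.json")
  jsonlite::write_json(
    list(seed = config$seed,
         fits = fit_report(fits),
         ranking = ranking),
    json_path, auto_unbox = TRUE, digits = NA
  )
  invisible(list(fits = fits, ranking = ranking,
                 paths = c(paths, json_path)))
}
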