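pc <- physical_constants()

test_that("energy density obeys the E_d = c*rho/4 identity and its limits", {
  lam <- 10e-6
  T22 <- celsius_to_kelvin(22)
  rho <- spectral_energy_density(lam, T22)
  # plane irradiance per metre equals c * rho / 4
  expect_equal(spectral_plane_irradiance(lam, T22, per = "m"),
               pc$light_speed_c * rho / 4, tolerance = 1e-12)
  # Bose factor vanishes as T -> 0+
  expect_equal(spectral_energy_density(lam, 1e-3), 0)
  # strictly increasing in temperature at fixed wavelength
  for (l in c(310e-9, 660e-9, 10e-6, 100e-6)) {
    ts <- c(150, 277.15, 295.15, 310.15, 600, 1200, 5778)
    vals <- spectral_energy_density(l, ts)
    expect_true(all(diff(vals) > 0))
    expect_gt(spectral_energy_density(l, 2 * 295.15),
              spectral_energy_density(l, 295.15))
  }
  expect_error(spectral_energy_density(-1e-6, 300), "wavelength")
  expect_error(spectral_energy_density(1e-6, -5), "> 0 K")
})

test_that("thermal IR irradiance at 10 um matches the reference table row", {
  # golden values: 0.0210 ... 0.0366 W m^-2 nm^-1 across 4-37 degC
  reference <- c(`4` = 0.0210, `12` = 0.0243, `16` = 0.0260,
                 `22` = 0.0288, `28` = 0.0318, `37` = 0.0366)
  got <- spectral_plane_irradiance(10e-6,
                                   celsius_to_kelvin(default_temperatures_c()))
  expect_equal(unname(got), unname(reference), tolerance = 0.01)
  # and against the independent formula oracle, tightly
  expect_equal(got, oracle_planck_nm(10e-6,
                                     celsius_to_kelvin(default_temperatures_c())),
               tolerance = 1e-12)
})

test_that("solar irradiance reproduces the verified reference cells", {
  expect_equal(solar_spectral_irradiance(310e-9), 0.91, tolerance = 0.015)
  expect_equal(solar_spectral_irradiance(470e-9), 1.77, tolerance = 0.015)
  expect_equal(solar_spectral_irradiance(660e-9), 1.52, tolerance = 0.015)
  expect_equal(solar_spectral_irradiance(10e-6), 2.86e-4, tolerance = 0.015)
  # dilution factor is exactly (R_sun/R_orbit)^2
  expect_equal(
    solar_spectral_irradiance(660e-9) /
      spectral_plane_irradiance(660e-9, pc$sun_temperature),
    (pc$sun_radius / pc$orbit_radius)^2,
    tolerance = 1e-12
  )
})

test_that("Wien peak matches the grid-argmax oracle and scales as 1/T", {
  expect_equal(round(peak_wavelength(5778) * 1e9), 501)
  # ambient environment peaks near 10 um
  lam22 <- peak_wavelength(celsius_to_kelvin(22))
  expect_gt(lam22, 9e-6)
  expect_lt(lam22, 10.5e-6)
  for (T in c(277.15, 295.15, 310.15, 5778)) {
    expect_equal(peak_wavelength(T), oracle_peak_grid(T), tolerance = 1e-4)
  }
  # lambda_max * T is constant (displacement law) and halves when T doubles
  ts <- seq(250, 6000, length.out = 12)
  prod <- peak_wavelength(ts) * ts
  expect_equal(prod, rep(prod[1L], length(ts)), tolerance = 1e-6)
  expect_equal(peak_wavelength(600), peak_wavelength(300) / 2,
               tolerance = 1e-9)
})

test_that("band integral recovers the Stefan-Boltzmann fourth-power law", {
  for (T in c(277.15, 295.15, 310.15, 5778)) {
    expect_equal(total_irradiance(T), stefan_boltzmann_total(T),
                 tolerance = 1e-3)
  }
  # frozen closed-form value at 22 degC with the package constants
  expect_equal(stefan_boltzmann_total(295.15), 430.7412, tolerance = 1e-5)
  expect_equal(total_irradiance(2 * 295.15) / total_irradiance(295.15), 16,
               tolerance = 0.005)
  expect_error(total_irradiance(295.15, lambda_lo = 1e-6, lambda_hi = 1e-7),
               "lambda")
})

test_that("photon flux is E*lambda/(hc) and preserves irradiance ratios", {
  hc <- pc$planck_h * pc$light_speed_c
  expect_equal(photon_flux(0.0288, 10e-6), 0.0288 * 1e-5 / hc)
  expect_equal(photon_flux(0, 660e-9), 0)
  expect_error(photon_flux(-1, 660e-9), "non-negative")
  # at fixed wavelength the flux ratio equals the irradiance ratio
  e1 <- spectral_plane_irradiance(10e-6, 295.15)
  e2 <- spectral_plane_irradiance(10e-6, 310.15)
  expect_equal(photon_flux(e1, 10e-6) / photon_flux(e2, 10e-6), e1 / e2,
               tolerance = 1e-12)
})

test_that("relative R:IR ratio is 1 at the reference and telescopes", {
  T22 <- celsius_to_kelvin(22)
  expect_equal(relative_r_ir_ratio(T22, T22), 1)
  # frozen oracle: Planck irradiance ratio at 10 um, 295.15 vs 310.15 K
  expect_equal(relative_r_ir_ratio(T22, celsius_to_kelvin(37)),
               0.7883969, tolerance = 1e-6)
  set.seed(7)
  for (i in 1:20) {
    t3 <- runif(3, 270, 320)
    expect_equal(
      relative_r_ir_ratio(t3[1], t3[2]) * relative_r_ir_ratio(t3[2], t3[3]),
      relative_r_ir_ratio(t3[1], t3[3]),
      tolerance = 1e-12
    )
  }
})

test_that("spectrum container validates its grid and writes deterministically", {
  sp <- blackbody_spectrum(295.15, wavelengths = default_wavelength_grid(100))
  expect_s3_class(sp, "spectrum")
  expect_equal(nrow(sp), 100)
  expect_true(all(diff(sp$wavelength_nm) > 0))
  expect_true(all(sp$irradiance_W_m2_nm >= 0))
  expect_error(blackbody_spectrum(295.15, wavelengths = c(2e-6, 1e-6)),
               "strictly increasing")

  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(sp, f1)
  write_spectrum_csv(sp, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(f1)[1],
                   "wavelength_nm,irradiance_W_m2_nm,temperature_K,source")

  solar <- blackbody_spectrum(wavelengths = default_wavelength_grid(100),
                              source = "solar")
  expect_equal(unique(solar$temperature_K), pc$sun_temperature)
})
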