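#' Light environment driving phytochrome photoconversion
#'
#' Photon fluxes and conversion coefficients entering the Pfr rate equation
#' \deqn{\frac{d[\mathrm{Pfr}]}{dt} = N_R \sigma_R [\mathrm{Pr}]
#'   - N_{FR} \sigma_{FR} [\mathrm{Pfr}] - N_{IR} k_{IR} [\mathrm{Pfr}].}
#' The photoconversion cross-sections follow \eqn{\sigma = 2.3 \epsilon \phi}
#' (extinction coefficient times quantum yield); `k_IR` is the effective IR
#' conversion coefficient with the same units contract. Only the products
#' `N * sigma` (reciprocal time) matter to the dynamics, so relative units
#' are used throughout: no absolute rate constant for the IR channel is
#' experimentally available, and the default calibration in
#' [dark_environment()] fixes the time unit instead.
#'
#' @param N_R,N_FR,N_IR Photon fluxes, photons m^-2 s^-1 nm^-1 (>= 0).
#' @param sigma_R,sigma_FR Photoconversion cross-sections, m^2 photon^-1
#'   (>= 0).
#' @param k_IR Effective IR conversion coefficient, m^2 photon^-1 (>= 0).
#' @return An object of class `light_environment`.
#' @export
light_environment <- function(N_R = 0, N_FR = 0, N_IR = 0,
                              sigma_R = 0, sigma_FR = 0, k_IR = 0) {
  env <- list(N_R = N_R, N_FR = N_FR, N_IR = N_IR,
              sigma_R = sigma_R, sigma_FR = sigma_FR, k_IR = k_IR)
  for (nm in names(env)) {
    v <- env[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("light environment field '", nm, "' must be a single finite ",
           "non-negative number", call. = FALSE)
    }
  }
  structure(env, class = "light_environment")
}

#' Dark thermal environment at a given temperature
#'
#' Builds the IR-only light environment experienced during dark reversion at
#' an ambient temperature: `N_R = N_FR = 0` and `N_IR` equal to the thermal
#' photon flux at 10 um from [ir_photon_flux()]. The coefficient `k_IR` is
#' calibrated so that the Pfr dark-reversion half-life at the 22 degC
#' reference equals `half_life_ref` relative time units (default 1); at other
#' temperatures the half-life then scales as the inverse IR flux ratio.
#'
#' @param temperature Ambient absolute temperature, K.
#' @inheritParams spectral_energy_density
#' @param half_life_ref Half-life assigned to the reference temperature, in
#'   relative time units.
#' @param temp_ref Reference absolute temperature, K (default 295.15 K,
#'   i.e. 22 degC).
#' @return A `light_environment` with only the IR channel active.
#' @examples
#' env22 <- dark_environment(celsius_to_kelvin(22))
#' dark_half_life(env22)  # 1 by calibration
#' @export
dark_environment <- function(temperature, constants = physical_constants(),
                             half_life_ref = 1,
                             temp_ref = celsius_to_kelvin(22)) {
  stopifnot(half_life_ref > 0)
  N_ref <- ir_photon_flux(temp_ref, constants)
  k_IR <- log(2) / (half_life_ref * N_ref)
  light_environment(N_IR = ir_photon_flux(temperature, constants), k_IR = k_IR)
}

#' Rate of change of Pfr
#'
#' Evaluates the three-term Pfr rate: red drive converts Pr to Pfr, far-red
#' and IR drives convert Pfr back to Pr. The implied d\[Pr\]/dt is the exact
#' negative, so total phytochrome is conserved.
#'
#' @param pfr,pr Current Pfr and Pr amounts (arbitrary concentration units,
#'   >= 0).
#' @param env A [light_environment()].
#' @return d\[Pfr\]/dt in concentration per relative time unit.
#' @export
pfr_rate <- function(pfr, pr, env) {
  stopifnot(inherits(env, "light_environment"), pfr >= 0, pr >= 0)
  env$N_R * env$sigma_R * pr -
    env$N_FR * env$sigma_FR * pfr -
    env$N_IR * env$k_IR * pfr
}

#' Simulate Pfr/Pr dynamics
#'
#' Integrates the Pfr rate equation over a constant light environment. For a
#' dark environment (`N_R = N_FR = 0`) the dynamics have the closed form
#' \eqn{[\mathrm{Pfr}](t) = [\mathrm{Pfr}]_{t_0} e^{-N_{IR} k_{IR} t}};
#' `method = "auto"` uses it, and otherwise (or on request) a fixed-step
#' classic 4th-order Runge-Kutta integration is run with at least 100 steps
#' per Pfr half-life.
#'
#' @param env A [light_environment()].
#' @param times Strictly increasing times (relative units); the first element
#'   is the initial time.
#' @param pfr0,pr0 Initial Pfr and Pr amounts. Default: all phytochrome in
#'   Pfr (the post-illumination state from which dark reversion starts).
#' @param method `"auto"` (closed form when dark, RK4 otherwise),
#'   `"closed_form"` (dark environments only) or `"rk4"`.
#' @return A data frame of class `pfr_trajectory` with columns `time`, `pfr`,
#'   `pr`, `pr_over_pfr`; the environment is attached as attribute
#'   `environment`.
#' @examples
#' env <- dark_environment(celsius_to_kelvin(22))
#' traj <- simulate_pfr(env, times = seq(0, 3, by = 0.1))
#' traj[traj$time == 1, ]  # half the Pfr remains after one half-life
#' @export
simulate_pfr <- function(env, times, pfr0 = 1, pr0 = 0,
                         method = c("auto", "closed_form", "rk4")) {
  method <- match.arg(method)
  stopifnot(inherits(env, "light_environment"), pfr0 >= 0, pr0 >= 0)
  if (length(times) < 1L || is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  dark <- env$N_R * env$sigma_R == 0 && env$N_FR * env$sigma_FR == 0
  if (method == "closed_form" && !dark) {
    stop("closed form requires a dark environment (no R or FR drive)",
         call. = FALSE)
  }
  use_closed <- method == "closed_form" || (method == "auto" && dark)
  t0 <- times[1L]
  total <- pfr0 + pr0
  if (use_closed) {
    pfr <- pfr0 * exp(-env$N_IR * env$k_IR * (times - t0))
    pr <- total - pfr
  } else {
    rates <- loss_rates(env)
    # step <= t_half/100 for the fastest decay channel present
    k_fast <- max(rates$loss, rates$gain)
    dt <- if (k_fast > 0) log(2) / k_fast / 100 else diff(range(times)) / 100
    grid <- sort(unique(c(times, seq(t0, max(times), by = dt))))
    sol <- deSolve::rk4(
      y = c(pfr = pfr0), times = grid,
      func = function(t, y, parms) list(pfr_rate(y[[1L]], total - y[[1L]], env)),
      parms = NULL
    )
    pfr <- sol[match(times, sol[, "time"]), "pfr"]
    if (anyNA(pfr)) {
      stop("integration failed to cover all requested times; ",
           "check the time grid", call. = FALSE)
    }
    pr <- total - pfr
  }
  structure(
    data.frame(
      time = times, pfr = pfr, pr = pr,
      pr_over_pfr = ifelse(pfr > 0, pr / pfr, Inf)
    ),
    environment = env,
    class = c("pfr_trajectory", "data.frame")
  )
}

loss_rates <- function(env) {
  list(
    gain = env$N_R * env$sigma_R,
    loss = env$N_FR * env$sigma_FR + env$N_IR * env$k_IR
  )
}

#' Pfr dark-reversion half-life
#'
#' Half-life of Pfr under IR-only decay, \eqn{t_{1/2} = \ln 2 / (N_{IR} k_{IR})}.
#' A zero IR drive gives an infinite half-life, returned as `Inf` with a
#' warning rather than an overflow.
#'
#' @param env A [light_environment()].
#' @return Half-life in relative time units; `Inf` if the IR channel is off.
#' @export
dark_half_life <- function(env) {
  stopifnot(inherits(env, "light_environment"))
  drive <- env$N_IR * env$k_IR
  if (drive == 0) {
    warning("IR drive is zero: Pfr does not revert; half-life is infinite")
    return(Inf)
  }
  log(2) / drive
}

#' Relative Pfr half-life across temperatures
#'
#' Because \eqn{t_{1/2} \propto 1 / N_{IR}}, the half-life at a query
#' temperature relative to the reference is the inverse ratio of IR photon
#' fluxes,
#' \deqn{\frac{t_{1/2}(T)}{t_{1/2}(T_{ref})} =
#'   \frac{N_{IR}(T_{ref})}{N_{IR}(T)},}
#' equivalently \eqn{\log t_{1/2}(T_1) - \log t_{1/2}(T_2) =
#' \log N_{IR}(T_2)/N_{IR}(T_1)} in any base. The relative half-life at the
#' reference is exactly 1; warmer environments revert faster (value < 1).
#'
#' @param temp_query Query absolute temperature(s), K.
#' @param temp_ref Reference absolute temperature, K (default 295.15 K).
#' @inheritParams spectral_energy_density
#' @return Dimensionless relative half-life.
#' @examples
#' relative_half_life(celsius_to_kelvin(37))  # ~0.79: faster reversion at 37 degC
#' relative_half_life(celsius_to_kelvin(4))   # ~1.38: slower at 4 degC
#' @export
relative_half_life <- function(temp_query, temp_ref = celsius_to_kelvin(22),
                               constants = physical_constants()) {
  ir_photon_flux(temp_ref, constants) / ir_photon_flux(temp_query, constants)
}

#' Pr/Pfr ratio during dark reversion
#'
#' For an all-Pfr initial state decaying in the dark, the closed form is
#' \deqn{\frac{[\mathrm{Pr}]}{[\mathrm{Pfr}]} =
#'   \frac{[\mathrm{Pfr}]_{t_0} - [\mathrm{Pfr}]}{[\mathrm{Pfr}]} =
#'   e^{N_{IR} k_{IR} t} - 1:}
#' 0 at t = 0, exactly 1 after one half-life, 3 after two.
#'
#' @param t Time(s) since the onset of darkness, relative units, >= 0.
#' @param env A [light_environment()]; must be dark (no R/FR drive).
#' @return Dimensionless Pr/Pfr ratio.
#' @export
pr_pfr_ratio <- function(t, env) {
  stopifnot(inherits(env, "light_environment"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  if (env$N_R * env$sigma_R > 0 || env$N_FR * env$sigma_FR > 0) {
    stop("Pr/Pfr closed form applies to dark environments only", call. = FALSE)
  }
  expm1(env$N_IR * env$k_IR * t)
}

#' Photostationary Pfr fraction
#'
#' Steady state of the Pfr rate equation under constant drive,
#' \deqn{\frac{[\mathrm{Pfr}]}{[\mathrm{Pfr}] + [\mathrm{Pr}]} =
#'   \frac{N_R \sigma_R}{N_R \sigma_R + N_{FR} \sigma_{FR} + N_{IR} k_{IR}}.}
#' Trajectories from [simulate_pfr()] relax exponentially to this fraction.
#'
#' @param env A [light_environment()]; at least one drive term must be
#'   positive.
#' @return Pfr fraction in \[0, 1\].
#' @export
photostationary_pfr_fraction <- function(env) {
  stopifnot(inherits(env, "light_environment"))
  r <- loss_rates(env)
  if (r$gain + r$loss == 0) {
    stop("all drive terms are zero: photostationary state undefined",
         call. = FALSE)
  }
  r$gain / (r$gain + r$loss)
}

#' Write a Pfr trajectory to CSV, with a JSON summary
#'
#' @param trajectory A `pfr_trajectory` from [simulate_pfr()].
#' @param path Output CSV path (`time, pfr, pr, pr_over_pfr`).
#' @param json_path Optional JSON path for a summary holding the dark
#'   half-life and photostationary Pfr fraction of the trajectory's
#'   environment.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path, json_path = NULL) {
  stopifnot(inherits(trajectory, "pfr_trajectory"))
  utils::write.csv(as.data.frame(trajectory), path,
                   row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    env <- attr(trajectory, "environment")
    summary <- list(
      half_life = suppressWarnings(dark_half_life(env)),
      photostationary_pfr_fraction = photostationary_pfr_fraction(env)
    )
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
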