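env22 <- dark_environment(celsius_to_kelvin(22))

test_that("rate equation has the right signs, zeros and conservation", {
  env <- light_environment(N_R = 2, N_FR = 1, N_IR = 3,
                           sigma_R = 0.5, sigma_FR = 0.25, k_IR = 0.1)
  # no Pfr and no red drive -> nothing moves
  expect_equal(pfr_rate(0, 1, light_environment(N_IR = 3, k_IR = 0.1,
                                                N_FR = 1, sigma_FR = 0.2)),
               0)
  # pure red drive builds Pfr
  expect_gt(pfr_rate(0.2, 0.8, light_environment(N_R = 2, sigma_R = 0.5)), 0)
  # dark reduces to -N_IR * k_IR * [Pfr]
  expect_equal(pfr_rate(0.7, 0.3, env22),
               -env22$N_IR * env22$k_IR * 0.7)
  # implied d[Pr]/dt is the exact negative: conservation at the rate level
  d_pfr <- pfr_rate(0.6, 0.4, env)
  d_pr <- env$N_FR * env$sigma_FR * 0.6 + env$N_IR * env$k_IR * 0.6 -
    env$N_R * env$sigma_R * 0.4
  expect_equal(d_pfr + d_pr, 0)
  expect_error(light_environment(N_R = -1), "non-negative")
})

test_that("dark reversion follows the closed-form exponential decay", {
  t12 <- dark_half_life(env22)
  expect_equal(t12, 1)  # calibration: half-life at 22 degC is one time unit
  times <- seq(0, 5 * t12, length.out = 101)
  traj <- simulate_pfr(env22, times)
  expect_equal(traj$pfr, exp(-log(2) * times), tolerance = 1e-12)
  # conservation along the trajectory
  expect_equal(traj$pfr + traj$pr, rep(1, length(times)), tolerance = 1e-12)
  # log-linearity: ln pfr vs t is a perfect line
  fit <- fit_linear(traj$time, log(traj$pfr))
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$slope, -log(2), tolerance = 1e-9)
  # half the Pfr remains at t = t_1/2
  at_half <- simulate_pfr(env22, c(0, t12))
  expect_equal(at_half$pfr[2], 0.5, tolerance = 1e-6)
})

test_that("RK4 integration matches the closed form over five half-lives", {
  t12 <- dark_half_life(env22)
  times <- seq(0, 5 * t12, length.out = 26)
  rk <- simulate_pfr(env22, times, method = "rk4")
  cf <- simulate_pfr(env22, times, method = "closed_form")
  expect_lt(max(abs(rk$pfr - cf$pfr)), 1e-6)  # of [Pfr]_0 = 1
  expect_equal(rk$pfr + rk$pr, rep(1, length(times)), tolerance = 1e-9)
})

test_that("trajectories relax to the photostationary Pfr fraction", {
  env <- light_environment(N_R = 4, N_FR = 1, N_IR = 2,
                           sigma_R = 0.6, sigma_FR = 0.3, k_IR = 0.15)
  phi <- photostationary_pfr_fraction(env)
  expect_equal(phi, (4 * 0.6) / (4 * 0.6 + 1 * 0.3 + 2 * 0.15))
  traj <- simulate_pfr(env, times = seq(0, 40, by = 0.5), pfr0 = 0, pr0 = 1)
  expect_equal(utils::tail(traj$pfr, 1), phi, tolerance = 1e-6)
  expect_equal(traj$pfr + traj$pr, rep(1, nrow(traj)), tolerance = 1e-9)
  # pure red drive saturates all phytochrome in Pfr
  red <- light_environment(N_R = 2, sigma_R = 1)
  expect_equal(photostationary_pfr_fraction(red), 1)
  long <- simulate_pfr(red, times = c(0, 20), pfr0 = 0.1, pr0 = 0.9)
  expect_equal(long$pfr[2] / (long$pfr[2] + long$pr[2]), 1, tolerance = 1e-6)
  expect_equal(photostationary_pfr_fraction(
    light_environment(N_FR = 1, sigma_FR = 1)), 0)
  # symmetric drives give one half
  expect_equal(photostationary_pfr_fraction(
    light_environment(N_R = 1, sigma_R = 1, N_FR = 1, sigma_FR = 0.5,
                      N_IR = 1, k_IR = 0.5)), 0.5)
  expect_error(photostationary_pfr_fraction(light_environment()), "undefined")
})

test_that("half-life identities: ln2 scaling, zero-drive signal, Pr/Pfr curve", {
  env <- light_environment(N_IR = log(2), k_IR = 1)
  expect_equal(dark_half_life(env), 1)
  # doubling the IR flux halves the half-life
  env2 <- light_environment(N_IR = 2 * log(2), k_IR = 1)
  expect_equal(dark_half_life(env2), 0.5)
  expect_warning(hl <- dark_half_life(light_environment()), "infinite")
  expect_identical(hl, Inf)

  t12 <- dark_half_life(env22)
  expect_equal(pr_pfr_ratio(0, env22), 0)
  expect_equal(pr_pfr_ratio(t12, env22), 1)
  expect_equal(pr_pfr_ratio(2 * t12, env22), 3)
  # exponential growth in t
  ts <- seq(0, 4, by = 0.25)
  expect_true(all(diff(pr_pfr_ratio(ts, env22)) > 0))
  expect_error(pr_pfr_ratio(-1, env22), ">= 0")
  expect_error(pr_pfr_ratio(1, light_environment(N_R = 1, sigma_R = 1)),
               "dark")
})

test_that("relative half-life tracks the inverse IR photon-flux ratio", {
  expect_equal(relative_half_life(celsius_to_kelvin(22)), 1)
  # frozen Planck-ratio oracles at 10 um
  expect_equal(relative_half_life(celsius_to_kelvin(37)), 0.7883969,
               tolerance = 1e-6)
  expect_equal(relative_half_life(celsius_to_kelvin(4)), 1.375216,
               tolerance = 1e-6)
  # warmer -> strictly shorter relative half-life
  rel <- relative_half_life(celsius_to_kelvin(default_temperatures_c()))
  expect_true(all(diff(rel) < 0))
  # consistency with the environment calibration: t12(T)/t12(22) = rel
  for (tc in c(4, 37)) {
    envT <- dark_environment(celsius_to_kelvin(tc))
    expect_equal(dark_half_life(envT),
                 relative_half_life(celsius_to_kelvin(tc)),
                 tolerance = 1e-12)
  }
})

test_that("trajectory writer emits CSV plus JSON summary", {
  traj <- simulate_pfr(env22, times = seq(0, 2, by = 0.5))
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_trajectory_csv(traj, csv, js)
  back <- utils::read.csv(csv)
  expect_equal(back$pfr, traj$pfr, tolerance = 1e-6)
  summ <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(summ$half_life, 1, tolerance = 1e-12)
  expect_equal(summ$photostationary_pfr_fraction, 0)
})
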