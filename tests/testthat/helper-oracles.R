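# Independent oracles kept deliberately separate from the implementation.

# Planck plane irradiance per nm, written out directly from the formula.
oracle_planck_nm <- function(lambda_m, T_K,
                             h = 6.626e-34, cc = 2.998e8, kB = 1.381e-23) {
  2 * pi * h * cc^2 / lambda_m^5 / (exp(h * cc / (lambda_m * kB * T_K)) - 1) * 1e-9
}

# Grid-argmax oracle for the Wien peak (no root-finding).
oracle_peak_grid <- function(T_K, n = 200001L) {
  # bracket the peak loosely around 2.9e-3 / T
  guess <- 2.9e-3 / T_K
  grid <- seq(guess / 5, guess * 5, length.out = n)
  grid[which.max(oracle_planck_nm(grid, T_K))]
}

# Normal-equations OLS oracle.
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  yhat <- X %*% beta
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(intercept = beta[1L], slope = beta[2L], r_squared = 1 - ss_res / ss_tot)
}

# Generative mean length of an archetype at the relative ratio r.
archetype_mean <- function(arch, r) arch$intercept + arch$slope * r

# Temperatures (degC) at which the 0.1 mm floor is statistically negligible
# for the archetype: generative mean more than 2 noise SDs above the floor,
# where the expected censoring shift is < 0.005 mm per condition.
truncation_free_temps <- function(arch, temps = default_temperatures_c()) {
  r <- relative_r_ir_ratio(celsius_to_kelvin(22), celsius_to_kelvin(temps))
  temps[archetype_mean(arch, r) > 0.1 + 2 * arch$noise_sd]
}
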