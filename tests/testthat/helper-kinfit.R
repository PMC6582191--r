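# Shared fixtures: ground-truth parameter sets and synthetic study designs
# used across the suite.  All datasets are generated in code at test time.

moser_truth <- function() {
  kinetic_params(mu_max = 0.1, Ks = 20, Y = 0.4, kd = 0.005, b = 2, n = 1.5)
}

monod_truth <- function() {
  kinetic_params(mu_max = 0.12, Ks = 15, Y = 0.4, kd = 0.005, b = 2)
}

zero_noise_ds <- function(model, truth, n_timepoints = 10,
                          duration_h = 96) {
  generate_synthetic(model, truth,
                     synth_design(n_timepoints = n_timepoints,
                                  duration_h = duration_h,
                                  n_replicates = 1, noise_sd_log10 = 0),
                     seed = 1)
}

noisy_ds <- function(model, truth, seed = 7, noise = 0.05) {
  generate_synthetic(model, truth,
                     synth_design(n_timepoints = 8, duration_h = 96,
                                  n_replicates = 3, noise_sd_log10 = noise),
                     seed = seed)
}

# Parameters of monod_truth() held fixed for the 2-parameter restricted
# problem (only mu_max and Ks free).
monod_fixed_yb <- function() list(Y = 0.4, kd = 0.005, b = 2)

# Independent fixed-step RK4 integrator for the Monod batch system.
# Deliberately self-contained (its own growth law, no package internals)
# so it can serve as an oracle for integrate_trajectory().
rk4_monod <- function(mu_max, Ks, Y, kd, S0, X0, t_end, dt = 1e-3) {
  rhs <- function(y) {
    S <- max(y[1], 0); X <- max(y[2], 0)
    mu <- if (S > 0) mu_max * S / (Ks + S) else 0
    c(-mu * X / Y, (mu - kd) * X)
  }
  y <- c(S0, X0)
  nstep <- round(t_end / dt)
  for (i in seq_len(nstep)) {
    k1 <- rhs(y)
    k2 <- rhs(y + dt / 2 * k1)
    k3 <- rhs(y + dt / 2 * k2)
    k4 <- rhs(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

# Log-spaced brute-force grid minimization of the restricted 2-parameter
# (mu_max, Ks) Monod compromise objective; the oracle for the global
# optimizer on the same box.
grid_min_restricted_monod <- function(dataset, n_grid = 200,
                                      mu_box = c(1e-3, 10),
                                      ks_box = c(1e-2, 1e3),
                                      fixed = monod_fixed_yb()) {
  mu_grid <- 10^seq(log10(mu_box[1]), log10(mu_box[2]), length.out = n_grid)
  ks_grid <- 10^seq(log10(ks_box[1]), log10(ks_box[2]), length.out = n_grid)
  best <- Inf
  for (mu in mu_grid) {
    for (ks in ks_grid) {
      p <- kinetic_params(mu_max = mu, Ks = ks, Y = fixed$Y, kd = fixed$kd,
                          b = fixed$b)
      pred <- integrate_trajectory("Monod", p, dataset$S0, dataset$C0,
                                   dataset$times)
      v <- of1(dataset, pred)$total
      if (v < best) best <- v
    }
  }
  best
}

# Bounds of the restricted 2-parameter problem, shared by optimizer and grid.
restricted_bounds <- function() list(mu_max = c(1e-3, 10),
                                     Ks = c(1e-2, 1e3))
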