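test_that("growth-off trajectory follows the closed-form decay solution", {
  p <- kinetic_params(mu_max = 0, Ks = 1, Y = 0.5, kd = 0.05, b = 2)
  times <- seq(0, 48, by = 4)
  tr <- integrate_trajectory("Monod", p, S0 = 10, C0 = 1, times)
  expect_false(tr$penalty)
  expect_equal(tr$X_pred, 2 * exp(-0.05 * times), tolerance = 1e-7)
  expect_equal(tr$S_pred, rep(10, length(times)), tolerance = 1e-9)
})

test_that("mass linkage holds without endogenous decay", {
  # Y*(S0 - S(t)) = X(t) - X0 for kd = 0, any growth law
  p <- kinetic_params(mu_max = 0.15, Ks = 10, Y = 0.45, kd = 0, b = 2,
                      n = 1.4)
  times <- seq(0, 96, length.out = 25)
  tr <- integrate_trajectory("Moser", p, S0 = 40, C0 = 0.1, times)
  X0 <- 2 * 0.1
  resid <- 0.45 * (40 - tr$S_pred) - (tr$X_pred - X0)
  expect_lt(max(abs(resid)) / max(tr$X_pred), 1e-6)
})

test_that("adaptive integration matches an independent fixed-step RK4 oracle", {
  tr <- integrate_trajectory(
    "Monod", kinetic_params(mu_max = 0.3, Ks = 5, Y = 0.4, kd = 0.01, b = 1),
    S0 = 50, C0 = 1, times = c(0, 24))
  oracle <- rk4_monod(0.3, 5, 0.4, 0.01, S0 = 50, X0 = 1, t_end = 24)
  # agreement to 4 significant digits
  expect_equal(tr$S_pred[2], oracle[1], tolerance = 5e-5)
  expect_equal(tr$X_pred[2], oracle[2], tolerance = 5e-5)
})

test_that("solution is converged in the integration tolerances", {
  p <- moser_truth()
  times <- c(0, 48, 96)
  t1 <- integrate_trajectory("Moser", p, 50, 0.05, times)
  t2 <- integrate_trajectory("Moser", p, 50, 0.05, times,
                             rtol = 5e-9, atol = 5e-11)
  rel <- abs(c(t1$S_pred - t2$S_pred, t1$X_pred - t2$X_pred)) /
    pmax(c(t2$S_pred, t2$X_pred), 1e-6)
  expect_lt(max(rel), 1e-5)
})

test_that("substrate never increases along a trajectory", {
  p <- monod_truth()
  tr <- integrate_trajectory("Monod", p, 50, 0.05,
                             times = seq(0, 120, length.out = 200))
  expect_true(all(diff(tr$S_pred) <= 1e-10))
})

test_that("integration failure yields a penalty-marked prediction", {
  # grotesquely stiff parameters provoke step-size collapse
  p <- kinetic_params(mu_max = 1e6, Ks = 1e-8, Y = 1e-6, kd = 0, b = 1e-4)
  tr <- integrate_trajectory("Monod", p, 50, 1e3,
                             times = seq(0, 96, length.out = 10))
  # either integrates (then finite) or flags the penalty; must not throw
  expect_true(is.logical(tr$penalty))
  if (!tr$penalty) expect_true(all(is.finite(tr$S_pred)))
})

test_that("noise-free synthetic data equal the true trajectory", {
  p <- moser_truth()
  ds <- generate_synthetic("Moser", p,
                           synth_design(n_replicates = 3,
                                        noise_sd_log10 = 0), seed = 5)
  tr <- integrate_trajectory("Moser", p, ds$S0, ds$C0, ds$times)
  expect_equal(ds$S_obs, tr$S_pred)
  expect_equal(ds$C_obs, tr$C_pred)
  expect_equal(ds$S_sd, rep(0, length(ds$times)))
})

test_that("synthetic generation is deterministic in the seed", {
  p <- moser_truth()
  d1 <- generate_synthetic("Moser", p, synth_design(), seed = 11)
  d2 <- generate_synthetic("Moser", p, synth_design(), seed = 11)
  d3 <- generate_synthetic("Moser", p, synth_design(), seed = 12)
  expect_identical(d1$S_obs, d2$S_obs)
  expect_identical(d1$C_obs, d2$C_obs)
  expect_false(identical(d1$S_obs, d3$S_obs))
})

test_that("log10-scale noise has the nominal spread (large-replicate check)", {
  p <- moser_truth()
  ds <- generate_synthetic(
    "Moser", p, synth_design(n_replicates = 1000, noise_sd_log10 = 0.05),
    seed = 3)
  sd_log <- apply(log10(ds$meta$replicates$S), 1, sd)
  expect_true(all(abs(sd_log - 0.05) / 0.05 < 0.15))
  expect_lt(abs(mean(sd_log) - 0.05) / 0.05, 0.05)
})

test_that("generation refuses durations that drive the truth to zero", {
  # fast Monod depletion: substrate underflows over a long horizon
  p <- kinetic_params(mu_max = 0.5, Ks = 1, Y = 0.5, kd = 0.01, b = 1)
  expect_error(
    generate_synthetic("Monod", p,
                       synth_design(S0 = 20, C0 = 0.5, duration_h = 400,
                                    n_timepoints = 8)),
    "shorter duration")
})

test_that("dataset validation enforces the contract", {
  expect_error(batch_dataset(c(0, 1, 2), c(1, 2, 0.5), c(1, 0, 2)),
               "row 2")
  expect_error(batch_dataset(c(0, 2, 1), c(3, 2, 1), c(1, 2, 3)),
               "increasing")
  expect_error(batch_dataset(c(1, 2, 3), c(3, 2, 1), c(1, 2, 3)),
               "must be 0")
})
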