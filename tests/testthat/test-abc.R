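# Brute-force reimplementation of the split-half potential scale reduction
# used as an oracle for gelman_rubin().
brute_R <- function(samples) {
  ng <- dim(samples)[2]
  keep <- (floor(ng / 2) + 1):ng
  x <- samples[, keep, , drop = FALSE]
  n <- dim(x)[2]; m <- dim(x)[1]
  Rp <- sapply(seq_len(dim(x)[3]), function(k) {
    xs <- x[, , k, drop = TRUE]
    W <- mean(apply(xs, 1, var))
    B <- n * var(rowMeans(xs))
    sqrt((n - 1) / n + B / (n * W))
  })
  max(Rp)
}

test_that("identical chains give the closed-form floor R = sqrt((n-1)/n)", {
  set.seed(1)
  n <- 40
  one <- rnorm(n)
  samples <- array(rep(one, each = 4), c(4, n, 1))
  expect_equal(as.numeric(gelman_rubin(samples, use_second_half = FALSE)),
               sqrt((n - 1) / n))
})

test_that("i.i.d. normal chains are declared converged (R < 1.05)", {
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    samples <- array(rnorm(6 * 5000), c(6, 5000, 1))
    if (as.numeric(gelman_rubin(samples)) < 1.05) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("offset chains are flagged as non-converged (R > 1.2)", {
  set.seed(2)
  samples <- array(c(rnorm(2000), rnorm(2000) + 10), c(2, 2000, 1))
  samples <- aperm(array(c(rnorm(2000), rnorm(2000) + 10), c(2000, 2, 1)),
                   c(2, 1, 3))
  expect_gt(as.numeric(gelman_rubin(samples)), 1.2)
})

test_that("gelman_rubin matches a brute-force reimplementation", {
  set.seed(3)
  for (i in 1:5) {
    samples <- array(rnorm(5 * 200 * 3, sd = runif(1, 0.5, 2)),
                     c(5, 200, 3))
    samples[2, , ] <- samples[2, , ] + runif(1, 0, 1)
    expect_equal(as.numeric(gelman_rubin(samples)), brute_R(samples))
  }
})

test_that("degenerate constant chains are flagged", {
  samples <- array(1, c(3, 50, 1))
  expect_equal(as.numeric(gelman_rubin(samples)), 1)  # B = W = 0: no spread
  samples[2, , 1] <- 2                                # offset constants
  expect_warning(r <- gelman_rubin(samples), "degenerate")
  expect_true(is.na(as.numeric(r)))
})

# one shared desk-scale ABC run on the restricted zero-noise problem,
# reused by several assertions below
abc_fixture <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      ds <- zero_noise_ds("Monod", monod_truth(), n_timepoints = 8)
      target <- abc_target(c(0, 0), epsilons = c(0.01, 0.01))
      val <<- list(
        ds = ds, target = target,
        hist = abc_sample("Monod", ds, target,
                          abc_config(n_chains = 6, n_generations = 6000,
                                     seed = 10, monitor_interval = 500),
                          bounds = restricted_bounds(),
                          fixed = monod_fixed_yb())
      )
    }
    val
  }
})

test_that("chains enter and stay inside the behavioral region", {
  fx <- abc_fixture()
  ng <- dim(fx$hist$fitness)[2]
  expect_true(all(fx$hist$fitness[, ng] >= 0))
  # monotone entry: once a chain is behavioral it never leaves
  for (ci in seq_len(nrow(fx$hist$fitness))) {
    f <- fx$hist$fitness[ci, ]
    entered <- which(f >= 0)[1]
    if (!is.na(entered)) expect_true(all(f[entered:ng] >= 0))
  }
})

test_that("posterior summary statistics lie within the tolerances of the target", {
  fx <- abc_fixture()
  ng <- dim(fx$hist$samples)[2]
  keep <- seq(floor(ng / 2) + 1, ng, by = 53)      # thinned second half
  stats_mat <- sapply(keep, function(g) {
    v <- fx$hist$samples[1, g, ]
    p <- kinetic_params(mu_max = v[["mu_max"]], Ks = v[["Ks"]],
                        Y = 0.4, kd = 0.005, b = 2)
    of_mo(fx$ds, integrate_trajectory("Monod", p, fx$ds$S0, fx$ds$C0,
                                      fx$ds$times))
  })
  mean_stats <- rowMeans(stats_mat)
  expect_true(all(abs(fx$target$observed_stats - mean_stats) <=
                    fx$target$epsilons))
})

test_that("a converged desk-scale run passes the R threshold and covers the truth", {
  fx <- abc_fixture()
  R <- gelman_rubin(log10(fx$hist$samples))
  expect_lt(as.numeric(R), 1.2)
  post <- summarize_posterior(fx$hist, "Monod", fx$ds)
  truth <- kin_params_vector(monod_truth())
  for (i in seq_len(nrow(post$params))) {
    pn <- post$params$parameter[i]
    expect_gte(truth[[pn]], post$params$q2.5[i])
    expect_lte(truth[[pn]], post$params$q97.5[i])
  }
  # predictive band contains the parameter band pointwise
  expect_true(all(post$bands$S_pred_lo <= post$bands$S_lo + 1e-12))
  expect_true(all(post$bands$S_pred_hi >= post$bands$S_hi - 1e-12))
  expect_true(all(post$bands$C_pred_lo <= post$bands$C_lo + 1e-12))
  expect_true(all(post$bands$C_pred_hi >= post$bands$C_hi - 1e-12))
  # parameter band contains the posterior-median trajectory
  expect_true(all(post$bands$S_median >= post$bands$S_lo &
                    post$bands$S_median <= post$bands$S_hi))
})

test_that("the mean-parameter trace stabilizes on a converged run", {
  fx <- abc_fixture()
  tr <- chain_mean_trace(fx$hist)
  expect_identical(nrow(tr), dim(fx$hist$samples)[2])
  # drift assessed on the log10 sampling scale of the parameters
  expect_lt(trace_drift(log10(tr), 0.2), 0.05)
  # constant chains give a constant trace
  const <- fx$hist
  const$samples[] <- 3
  expect_true(all(chain_mean_trace(const) == 3))
})

test_that("sampling is bit-identical under a repeated seed", {
  ds <- zero_noise_ds("Monod", monod_truth(), n_timepoints = 8)
  target <- abc_target(c(0, 0), epsilons = c(0.05, 0.05))
  cfg <- abc_config(n_chains = 3, n_generations = 300, seed = 4,
                    monitor_interval = 150)
  h1 <- abc_sample("Monod", ds, target, cfg, bounds = restricted_bounds(),
                   fixed = monod_fixed_yb())
  h2 <- abc_sample("Monod", ds, target, cfg, bounds = restricted_bounds(),
                   fixed = monod_fixed_yb())
  expect_identical(h1$samples, h2$samples)
  expect_identical(h1$fitness, h2$fitness)
})

test_that("huge tolerances reduce the posterior to the prior (2-D toy limit)", {
  ds <- zero_noise_ds("Monod", monod_truth(), n_timepoints = 8)
  target <- abc_target(c(0, 0), epsilons = c(1e6, 1e6))
  hist <- abc_sample("Monod", ds, target,
                     abc_config(n_chains = 6, n_generations = 4000,
                                seed = 8, monitor_interval = 1000),
                     bounds = restricted_bounds(),
                     fixed = monod_fixed_yb())
  expect_gt(hist$acceptance_rate, 0.95)
  # on the log10 sampling scale the prior is uniform over the box:
  # posterior means should sit near the box midpoints
  z <- log10(hist$samples)
  for (pn in c("mu_max", "Ks")) {
    box <- log10(restricted_bounds()[[pn]])
    mid <- mean(box); width <- diff(box)
    expect_lt(abs(mean(z[, , pn]) - mid) / width, 0.05)
  }
})

test_that("the posterior concentrates as the tolerance is halved", {
  ds <- zero_noise_ds("Monod", monod_truth(), n_timepoints = 8)
  sds <- sapply(c(0.2, 0.1, 0.05), function(eps) {
    hist <- abc_sample("Monod", ds, abc_target(c(0, 0), epsilons = eps),
                       abc_config(n_chains = 6, n_generations = 2000,
                                  seed = 12, monitor_interval = 1000),
                       bounds = restricted_bounds(),
                       fixed = monod_fixed_yb())
    ng <- dim(hist$samples)[2]
    keep <- (ng / 2 + 1):ng
    mean(c(sd(log10(hist$samples[, keep, "mu_max"])),
           sd(log10(hist$samples[, keep, "Ks"]))))
  })
  expect_true(all(diff(sds) < 0))
})

test_that("an unreachable tolerance produces a structured failure", {
  ds <- zero_noise_ds("Monod", monod_truth(), n_timepoints = 8)
  # statistics can never be within 1e-9 of an unattainable -1 shifted target
  target <- abc_target(c(5000, 5000), epsilons = c(1e-9, 1e-9))
  expect_error(
    abc_sample("Monod", ds, target,
               abc_config(n_chains = 3, n_generations = 50, seed = 1,
                          monitor_interval = 25),
               bounds = restricted_bounds(), fixed = monod_fixed_yb()),
    "behavioral")
})
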