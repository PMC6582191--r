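make_pred <- function(times, S, C) {
  structure(list(times = times, S_pred = S, X_pred = S * 0 + 1, C_pred = C,
                 penalty = FALSE), class = "trajectory_prediction")
}

make_ds <- function(times, S, C) batch_dataset(times, S, C)

test_that("log10 residuals follow the decade arithmetic", {
  ds <- make_ds(c(0, 1), c(10, 1), c(1, 1))
  pred <- make_pred(c(0, 1), c(1, 10), c(1, 1))
  r <- residuals_log10(ds, pred)
  expect_equal(r$r_subs, c(1, -1))
  expect_equal(r$r_cells, c(0, 0))
  expect_equal(of1(ds, pred)$ssr_subs, 2)
  # perfect prediction
  r0 <- residuals_log10(ds, make_pred(c(0, 1), c(10, 1), c(1, 1)))
  expect_equal(r0$r_subs, c(0, 0))
  # uniform decade offset
  rd <- residuals_log10(ds, make_pred(c(0, 1), c(100, 10), c(1, 1)))
  expect_equal(rd$r_subs, c(-1, -1))
})

test_that("of1 decomposes into percent contributions summing to 100", {
  ds <- make_ds(c(0, 1, 2), c(10, 1, 1), c(1, 1, 1))
  pred <- make_pred(c(0, 1, 2), c(1, 10, 1), c(1, 1, 1))
  v <- of1(ds, pred)
  expect_equal(v$ssr_subs, 2)
  expect_equal(v$ssr_cells, 0)
  expect_equal(v$total, 2)
  expect_equal(v$pct_subs, 100)
  expect_equal(v$pct_cells, 0)
  expect_identical(v$pct_subs + v$pct_cells, 100)
  # degenerate zero total: 50/50 convention, flagged
  v0 <- of1(ds, make_pred(c(0, 1, 2), c(10, 1, 1), c(1, 1, 1)))
  expect_equal(v0$total, 0)
  expect_true(v0$degenerate)
  expect_identical(c(v0$pct_subs, v0$pct_cells), c(50, 50))
})

test_that("objective total is invariant to common rescaling of data and fit", {
  times <- c(0, 1, 2, 3)
  S <- c(50, 20, 5, 1); Sp <- S * c(1.1, 0.9, 1.2, 1)
  C <- c(0.1, 0.5, 2, 3); Cp <- C * c(0.95, 1.1, 1, 1.05)
  v1 <- of1(make_ds(times, S, C), make_pred(times, Sp, Cp))
  v2 <- of1(make_ds(times, S * 7, C * 3), make_pred(times, Sp * 7, Cp * 3))
  expect_equal(v1$total, v2$total)
})

test_that("objective total is symmetric in the variable labels", {
  times <- c(0, 1, 2)
  a_obs <- c(5, 3, 2); a_pred <- c(4, 3.5, 2)
  b_obs <- c(0.2, 1, 2); b_pred <- c(0.25, 0.9, 2.2)
  v1 <- of1(make_ds(times, a_obs, b_obs), make_pred(times, a_pred, b_pred))
  v2 <- of1(make_ds(times, b_obs, a_obs), make_pred(times, b_pred, a_pred))
  expect_equal(v1$total, v2$total)
  expect_equal(v1$pct_subs, v2$pct_cells)
})

test_that("of_mo equals the of1 components", {
  times <- c(0, 1, 2, 3)
  ds <- make_ds(times, c(50, 20, 5, 1), c(0.1, 0.5, 2, 3))
  pred <- make_pred(times, c(45, 22, 5, 1.2), c(0.12, 0.4, 2, 3))
  v <- of1(ds, pred)
  expect_equal(unname(of_mo(ds, pred)), c(v$ssr_subs, v$ssr_cells))
})

test_that("penalty-marked predictions map to the 1e12 sentinel total", {
  ds <- make_ds(c(0, 1), c(10, 1), c(1, 1))
  pen <- structure(list(times = c(0, 1), S_pred = c(NA, NA),
                        X_pred = c(NA, NA), C_pred = c(NA, NA),
                        penalty = TRUE), class = "trajectory_prediction")
  v <- of1(ds, pen)
  expect_equal(v$total, 1e12)
  expect_true(v$penalty)
})

test_that("ABC fitness implements the min over tolerance-shifted distances", {
  t1 <- abc_target(c(1, 2), epsilons = c(0.1, 0.1))
  expect_equal(of2_abc(c(1, 2), t1), 0.1)
  expect_equal(of2_abc(c(1.05, 2.5), t1), -0.4)
  expect_error(of2_abc(c(1), t1), "length")
  # brute-force equivalence over random cases
  set.seed(42)
  for (i in 1:25) {
    m <- sample(2:5, 1)
    S <- runif(m, 0, 3); Sh <- runif(m, 0, 3); eps <- runif(m, 0.01, 1)
    tt <- abc_target(S, eps)
    brute <- min(vapply(seq_len(m),
                        function(j) eps[j] - abs(S[j] - Sh[j]), 0))
    expect_equal(of2_abc(Sh, tt), brute)
  }
})

test_that("ABC fitness is monotone in the tolerances", {
  set.seed(9)
  for (i in 1:10) {
    S <- runif(2, 0, 3); Sh <- runif(2, 0, 3); eps <- runif(2, 0.05, 0.5)
    base <- of2_abc(Sh, abc_target(S, eps))
    for (j in 1:2) {
      eps2 <- eps; eps2[j] <- eps2[j] * 2
      expect_gte(of2_abc(Sh, abc_target(S, eps2)), base)
    }
  }
})

test_that("default ABC tolerances follow the 5 percent / floor rule", {
  tt <- abc_target(c(2, 0.05))
  expect_equal(tt$epsilons, c(0.1, 0.01))
})
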