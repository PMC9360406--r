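test_that("rate constants respect the fibrinogen dependence", {
  m <- rate_model()
  expect_equal(unname(rate_constants(m, m$fib_ref)),
               c(m$k_at_ref, m$k_a2m_ref))
  mc <- rate_model(fib_dependence = "constant")
  expect_equal(rate_constants(mc, 1)[["k_at"]], rate_constants(mc, 8)[["k_at"]])
  # monotone non-increasing over a fibrinogen grid, g in (0, 1]
  grid <- seq(0, 8, 0.25)
  kat <- vapply(grid, function(fg) rate_constants(m, fg)[["k_at"]], 0)
  expect_true(all(diff(kat) <= 1e-15))
  expect_true(all(kat <= m$k_at_ref + 1e-15 & kat > 0))
  expect_gte(rate_constants(m, 2)[["k_at"]], rate_constants(m, 4)[["k_at"]])
  expect_error(rate_constants(m, -1), "non-negative")
})

test_that("thrombin decay capacity is the inhibitor-weighted rate sum", {
  expect_equal(thrombin_decay_capacity(round_factors(), round_model()),
               0.5 + 0.15)
  z <- plasma_factors(0, 0, 2.9)
  expect_equal(thrombin_decay_capacity(z, rate_model()), 0)
  # strictly increasing in AT and a2M, non-increasing in fibrinogen
  m <- rate_model()
  tdc <- function(at, a2m, fib) thrombin_decay_capacity(plasma_factors(at, a2m, fib), m)
  expect_gt(tdc(120, 2.6, 2.9), tdc(110, 2.6, 2.9))
  expect_gt(tdc(113, 3.0, 2.9), tdc(113, 2.2, 2.9))
  expect_lte(tdc(113, 2.6, 4.0), tdc(113, 2.6, 2.9))
})

test_that("excess-inhibitor decay matches the closed form to solver tolerance", {
  f <- round_factors(); m <- round_model(stoich = FALSE)
  tr <- simulate_inactivation(f, m, seq(0, 12, 0.05), bolus = 100)
  expect_equal(tr$t_free[tr$time == 2], 100 * exp(-1.3), tolerance = 1e-7)
  rel <- abs(tr$t_free - 100 * exp(-0.65 * tr$time)) / (100 * exp(-0.65 * tr$time))
  expect_lt(max(rel), 1e-6)
  # fitted log-linear rate recovers the TDC
  expect_equal(fit_decay_rate(tr$time, tr$t_free), 0.65, tolerance = 1e-3)
})

test_that("a zero bolus gives an all-zero trajectory", {
  tr <- simulate_inactivation(round_factors(), round_model(), seq(0, 5, 0.1))
  expect_true(all(tr$t_free == 0 & tr$t_at == 0 & tr$t_a2m == 0))
})

test_that("mass balance holds for random factor/bolus combinations", {
  set.seed(101)
  for (i in 1:8) {
    f <- plasma_factors(runif(1, 60, 160), runif(1, 1, 5), runif(1, 1.5, 5))
    m <- rate_model(stoichiometric_depletion = i %% 2 == 0)
    tr <- simulate_inactivation(f, m, seq(0, 15, 0.05),
                                bolus = runif(1, 10, 800))
    expect_lt(conservation_gap(tr), 1e-6)
  }
})

test_that("mass balance holds with a source term", {
  f <- median_factors(); m <- rate_model()
  tr <- simulate_inactivation(f, m, seq(0, 25, 0.05),
                              source = function(t) 900 * dgamma(t - 2, 3, scale = 1.2))
  expect_lt(conservation_gap(tr), 1e-6)
  expect_true(all(diff(tr$t_at) >= 0) && all(diff(tr$t_a2m) >= 0))
  expect_true(all(diff(tr$at_remaining) <= 0) && all(diff(tr$a2m_remaining) <= 0))
})

test_that("fitted decay rate is invariant to the bolus size in excess mode", {
  f <- round_factors(); m <- round_model(stoich = FALSE)
  rates <- vapply(c(1, 10, 100, 1000), function(b) {
    tr <- simulate_inactivation(f, m, seq(0, 8, 0.05), bolus = b)
    fit_decay_rate(tr$time, tr$t_free)
  }, 0)
  expect_lt(diff(range(rates)) / mean(rates), 0.005)
})

test_that("complex partition in excess mode equals the rate-weighted inhibitor ratio", {
  f <- round_factors(); m <- round_model(stoich = FALSE)
  tr <- simulate_inactivation(f, m, seq(0, 40, 0.05), bolus = 200)
  want <- (2e-4 * 2500) / (5e-5 * 3000)
  expect_equal(tr$t_at[nrow(tr)] / tr$t_a2m[nrow(tr)], want, tolerance = 1e-6)
})

test_that("stoichiometric depletion exhausts a scarce inhibitor", {
  # [AT]0 = 50 nM << bolus 500 nM, no a2M: all AT ends up in complexes and
  # the excess thrombin survives
  f <- plasma_factors(2, 0, 2.9)
  m <- rate_model(k_at_ref = 2e-4, k_a2m_ref = 0, fib_dependence = "constant",
                  at_nM_per_pct = 25, stoichiometric_depletion = TRUE)
  tr <- simulate_inactivation(f, m, seq(0, 120, 0.05), bolus = 500)
  n <- nrow(tr)
  expect_equal(tr$t_at[n], 50, tolerance = 1e-4)
  expect_equal(tr$t_free[n], 450, tolerance = 1e-4)
  expect_lt(conservation_gap(tr), 1e-6)
  # fine-grid oracle at a tenth of the step agrees
  tr_fine <- simulate_inactivation(f, m, seq(0, 20, 0.005), bolus = 500)
  i <- match(round(tr_fine$time, 8), round(tr$time, 8), nomatch = 0)
  expect_equal(tr_fine$t_at[i > 0], tr$t_at[i[i > 0]], tolerance = 1e-8)
})

test_that("trajectories agree with an independent general-purpose ODE solver", {
  f <- median_factors(); m <- rate_model()
  k <- rate_constants(m, f$fib_gL)
  rhs <- function(t, y, parms) {
    f1 <- k[["k_at"]] * y[4] * y[1]
    f2 <- k[["k_a2m"]] * y[5] * y[1]
    list(c(-f1 - f2, f1, f2, -f1, -f2))
  }
  y0 <- c(T = 300, TAT = 0, Ta2M = 0, AT = 113 * 24, A2M = 2600)
  ode <- deSolve::ode(y0, seq(0, 10, 0.05), rhs, NULL,
                      rtol = 1e-10, atol = 1e-10)
  tr <- simulate_inactivation(f, m, seq(0, 10, 0.05), bolus = 300)
  expect_equal(tr$t_free, unname(ode[, "T"]), tolerance = 1e-6)
  expect_equal(tr$t_at, unname(ode[, "TAT"]), tolerance = 1e-6)
})
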