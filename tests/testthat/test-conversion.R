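test_that("the local-polynomial derivative is exact for low-degree polynomials", {
  tt <- seq(0, 10, 0.1)
  lin <- thrombin_curve(tt, 10 * tt, truncated = TRUE)
  expect_equal(differentiate_curve(lin, window = 11),
               rep(10, length(tt)), tolerance = 1e-10)
  quad <- thrombin_curve(tt, tt^2, truncated = TRUE)
  expect_lt(max(abs(differentiate_curve(quad, window = 11) - 2 * tt)), 1e-9)
})

test_that("derivative window validation rejects bad windows", {
  cv <- triangle_curve()
  expect_error(differentiate_curve(cv, window = 4), "odd")
  expect_error(differentiate_curve(cv, window = 3), "odd|>= 5")
  expect_error(differentiate_curve(cv, window = 151), "half the record")
})

test_that("smoothing beats naive finite differences on a noisy signal", {
  tt <- seq(0, 20, 0.05)
  set.seed(7)
  noisy <- 50 * sin(tt) + 60 + rnorm(length(tt), 0, 2)
  cv <- thrombin_curve(tt, noisy, noise_floor = 20, truncated = TRUE)
  d_sg <- differentiate_curve(cv)
  d_naive <- c(NA, diff(noisy, lag = 2) / 0.1, NA)
  true_d <- 50 * cos(tt)
  rmse <- function(x) sqrt(mean((x - true_d)^2, na.rm = TRUE))
  expect_lt(rmse(d_sg), rmse(d_naive))
})

test_that("the derivative window adapts to the estimated noise level", {
  tt <- seq(0, 20, 0.05)
  clean <- 300 * dgamma(tt, 3, 1)
  expect_lt(estimate_noise_sd(clean), 0.1)
  set.seed(5)
  noisy <- clean + rnorm(length(tt), 0, 5)
  expect_equal(estimate_noise_sd(noisy), 5, tolerance = 0.2)
  w_clean <- choose_derivative_window(clean, 0.05)
  set.seed(6)
  w_quiet <- choose_derivative_window(clean + rnorm(length(tt), 0, 0.2), 0.05)
  w_noisy <- choose_derivative_window(noisy, 0.05)
  expect_equal(w_clean, 5)   # pristine record: minimal window
  expect_equal(w_quiet, 11)  # 0.5 min at dt = 0.05
  expect_equal(w_noisy, 41)  # 2.0 min
})

test_that("an all-zero curve extracts to zero conversion and zero complexes", {
  tt <- seq(0, 10, 0.1)
  cv <- thrombin_curve(tt, rep(0, length(tt)))
  ex <- extract_conversion(cv, median_factors(), rate_model())
  expect_true(all(abs(ex$conversion$rate) < 1e-12))
  td <- summarize_td(ex$conversion, ex$trajectory, 0.9)
  expect_equal(td$pc_tot, 0)
  expect_equal(td$pc_max, 0)
  expect_equal(td$t_at, 0)
  expect_equal(td$t_a2m, 0)
})

test_that("without inactivation the conversion rate is the thrombin derivative", {
  tt <- seq(0, 10, 0.1)
  cv <- thrombin_curve(tt, pmin(100 * tt, 300))
  m0 <- rate_model(k_at_ref = 0, k_a2m_ref = 0, fib_dependence = "constant")
  ex <- extract_conversion(cv, median_factors(), m0)
  mid_ramp <- ex$conversion$time > 0.5 & ex$conversion$time < 2.5
  plateau <- ex$conversion$time > 3.5
  expect_equal(ex$conversion$rate[mid_ramp],
               rep(100, sum(mid_ramp)), tolerance = 1e-9)
  expect_lt(max(abs(ex$conversion$rate[plateau])), 1e-9)
  td <- summarize_td(ex$conversion, ex$trajectory, 0)
  # pc_tot equals the final thrombin concentration exactly in this limit
  expect_equal(td$pc_tot, 300)
})

test_that("extraction inverts the forward simulation (round trip)", {
  f <- median_factors(); m <- rate_model()
  shape <- conversion_shape(950, 2, 3, dgamma(2, 3) * 950 / 200)  # pc_max 200
  sim <- forward_simulate_tg(shape, f, m, seq(0, 40, 0.05))
  expect_equal(sim$truth$pc_max, 200, tolerance = 1e-12)
  ex <- extract_conversion(sim$curve, f, m)
  true_rate <- conversion_rate(shape, ex$conversion$time)
  expect_lt(max(abs(ex$conversion$rate - true_rate)) / 200, 0.01)
  td <- summarize_td(ex$conversion, ex$trajectory,
                     thrombin_decay_capacity(f, m))
  expect_equal(td$pc_tot, 950, tolerance = 0.02)
  expect_equal(td$pc_max, 200, tolerance = 0.02)
  expect_equal(td$t_at, sim$truth$t_at, tolerance = 0.02)
  expect_equal(td$t_a2m, sim$truth$t_a2m, tolerance = 0.02)
  # complex split matches the forward simulation
  expect_equal(td$t_at / td$t_a2m, sim$truth$t_at / sim$truth$t_a2m,
               tolerance = 0.02)
})

test_that("summarizing a rectangular rate gives its area and height", {
  # build a synthetic conversion curve directly
  tt <- seq(0, 12, 0.1)
  rate <- ifelse(tt >= 1 & tt < 10, 100, 0)
  conv <- structure(list(time = tt, rate = rate,
                         provenance = list(window = 11, degree = 3,
                                           noise_sd = 0, tail_extended = FALSE,
                                           record_samples = length(tt),
                                           residual_end_nM = 0,
                                           negative_mass_fraction = 0)),
                    class = "conversion_curve")
  dt <- 0.1
  cum <- c(0, cumsum((rate[-1] + rate[-length(rate)]) / 2)) * dt
  traj <- structure(
    data.frame(time = tt, t_free = rep(0, length(tt)), t_at = cum,
               t_a2m = 0 * cum, at_remaining = 0, a2m_remaining = 0,
               cum_source = cum),
    class = c("inactivation_trajectory", "data.frame"), bolus = 0)
  td <- summarize_td(conv, traj, 0.9)
  expect_equal(td$pc_tot, 900)
  expect_equal(td$pc_max, 100)
})

test_that("tail extrapolation appends the right exponential area", {
  tt <- seq(0, 6, 0.05)
  dec <- 100 * exp(-0.7 * tt)  # residual ~ 1.5 nM at the end
  cv <- thrombin_curve(tt, dec, truncated = TRUE)
  residual <- dec[length(dec)]
  ext <- extrapolate_tail(cv, 0.7, 10)
  expect_true("tail_extended" %in% ext$flags)
  app <- ext$thrombin[ext$time >= 6]
  area <- sum((app[-1] + app[-length(app)]) / 2) * 0.05
  expect_equal(area, residual / 0.7, tolerance = 5e-3)
  # ten half-lives of extra record
  expect_equal(max(ext$time), 6 + ceiling(10 * log(2) / 0.7 / 0.05) * 0.05,
               tolerance = 1e-8)
  # zero residual: unchanged
  z <- thrombin_curve(tt, rep(0, length(tt)))
  expect_identical(extrapolate_tail(z, 0.7), z)
  expect_error(extrapolate_tail(cv, 0), "> 0")
})

test_that("tail extension recovers complexes lost to record truncation", {
  f <- median_factors(); m <- rate_model()
  # sharp pulse, record cut while ~10% of peak thrombin remains
  shape <- conversion_shape(900, 1, 3, 0.3)
  sim <- forward_simulate_tg(shape, f, m, seq(0, 30, 0.05))
  cut <- sim$curve$time <= 8
  short <- thrombin_curve(sim$curve$time[cut], sim$curve$thrombin[cut],
                          truncated = TRUE)
  ex <- extract_conversion(short, f, m, tail = "on")
  td <- summarize_td(ex$conversion, ex$trajectory,
                     thrombin_decay_capacity(f, m))
  complete <- sim$truth$t_at + sim$truth$t_a2m
  expect_lt(abs((td$t_at + td$t_a2m) - complete) / sim$truth$pc_tot, 0.005)
  expect_true(td$diagnostics$tail_extended)
  expect_gt(td$diagnostics$tail_complexes_nM, 5)
  # without the tail the complexes are biased low
  ex0 <- extract_conversion(short, f, m, tail = "off")
  td0 <- summarize_td(ex0$conversion, ex0$trajectory,
                      thrombin_decay_capacity(f, m))
  expect_lt(td0$t_at + td0$t_a2m, td$t_at + td$t_a2m)
})

test_that("a TM-like scaling of the input pulse scales extracted PCtot linearly", {
  f <- median_factors(); m <- rate_model()
  base <- conversion_shape(933, 2.1, 3, 1.2)
  scaled <- conversion_shape(933 * 0.56, 2.1, 3, 1.2)
  td_of <- function(sh) {
    sim <- forward_simulate_tg(sh, f, m, seq(0, 40, 0.05))
    res <- thrombin_dynamics(sim$curve, f, m)
    res$td
  }
  td1 <- td_of(base); td2 <- td_of(scaled)
  expect_equal(td2$pc_tot / td1$pc_tot, 0.56, tolerance = 0.01)
})
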