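test_that("photic activation is zero in darkness, scale-valued at I0, monotone in lux", {
  cp <- circadian_params()
  expect_equal(photic_activation(0, cp), 0)
  expect_equal(photic_activation(cp$i_0, cp), cp$alpha_0)
  for (p in seq(0.5, 0.7, by = 0.05)) {
    cpp <- circadian_params(p = p)
    expect_gt(photic_activation(1000, cpp), photic_activation(100, cpp))
  }
  expect_error(photic_activation(-1, cp), "non-negative")
})

test_that("Process L relaxes to its closed-form fixed point in constant light", {
  cp <- circadian_params()
  expect_equal(process_l_derivative(0, 0, cp), 0)       # dark fixed point
  expect_lt(process_l_derivative(0.3, 0, cp), 0)        # pure decay
  # long integration vs two-rate balance n* = alpha / (alpha + beta)
  lux <- 200
  const <- light_schedule(data.frame(t_start = 0, t_end = 120,
                                     lux_start = lux, lux_end = lux))
  res <- simulate(const, cp, awake_params(),
                  initial = list(x = -1, xc = 0, n = 0, H = 1, asleep = FALSE))
  a <- photic_activation(lux, cp)
  expect_equal(res$n[length(res$n)], a / (a + cp$beta), tolerance = 1e-9)
})

test_that("photic drive vanishes without light or with a saturated retina", {
  cp <- circadian_params()
  expect_equal(light_drive(0.5, -0.5, 0.3, 0, cp), 0)
  expect_equal(light_drive(0.5, -0.5, 1, 500, cp), 0)
  expect_gt(light_drive(0, 0, 0, 500, cp), 0)
})

test_that("homeostatic pressure decays exponentially during sleep", {
  sp <- sleep_params(mu = 2, delta = 1.9, c_a = 0)
  expect_equal(homeostat_derivative(0, TRUE, sp), 0)
  expect_lt(homeostat_derivative(5, TRUE, sp), 0)
  expect_gt(homeostat_derivative(5, FALSE, sp), 0)
  # integrator trajectory vs closed form H0 exp(-t / chi)
  dark <- dark_schedule(2)
  res <- simulate(dark, circadian_params(), sp,
                  initial = list(x = -1, xc = 0, n = 0, H = 18, asleep = TRUE),
                  t_end = 24)
  expect_true(all(res$asleep))
  expect_equal(res$H, 18 * exp(-res$time / sp$chi), tolerance = 1e-6)
})

test_that("sleep thresholds keep a constant gap and follow the oscillator", {
  sp <- sleep_params()
  x <- seq(-1, 1, by = 0.1)
  th <- sleep_thresholds(x, sp)
  expect_equal(th$upper - th$lower, rep(sp$delta, length(x)))
  sp0 <- sleep_params(c_a = 0)
  th0 <- sleep_thresholds(x, sp0)
  expect_equal(th0$upper, rep(sp0$mu, length(x)))
  expect_equal(th0$lower, rep(sp0$mu - sp0$delta, length(x)))
})

test_that("transition rule gates sleep on pressure and light", {
  sp <- sleep_params()  # wake_lux_threshold 0.5
  up <- 19; lo <- 13
  # pressure above threshold but lights on: sleep prevented
  expect_false(transition_rule(FALSE, 20, up, lo, lux = 90, sp))
  # pressure above threshold in darkness: sleep onset
  expect_true(transition_rule(FALSE, 20, up, lo, lux = 0, sp))
  # asleep, pressure mid-range, bright light: forced wake
  expect_false(transition_rule(TRUE, 16, up, lo, lux = 1000, sp))
  # asleep, pressure at lower threshold: spontaneous wake
  expect_false(transition_rule(TRUE, 12.9, up, lo, lux = 0, sp))
  # asleep, pressure mid-range, darkness: stay asleep
  expect_true(transition_rule(TRUE, 16, up, lo, lux = 0, sp))
})

test_that("CBTmin detection matches closed forms and a dense argmin oracle", {
  t <- seq(0, 72, by = 0.01)
  mins <- cbt_min_times(t, cos(2 * pi * t / 24))
  expect_equal(mins, c(12, 36, 60), tolerance = 1e-6)
  expect_equal(cbt_min_times(t[t <= 20], cos(2 * pi * t[t <= 20] / 24)),
               numeric(0))
  # refined minima of a simulated trajectory sit within one grid step of the
  # per-cycle brute-force argmin
  eq <- equilibrate(n_days = 20)
  res <- eq$result
  for (m in res$cbt_min[-1]) {
    w <- which(res$time > m - 2 & res$time < m + 2)
    brute <- res$time[w][which.min(res$x[w])]
    expect_lt(abs(m - brute), 0.01 + 1e-9)
  }
  # entrained steady state: successive minima 24 h apart to the minute
  gaps <- diff(tail(res$cbt_min, 4))
  expect_true(all(abs(gaps - 24) < 1 / 60))
})

test_that("DLMO precedes CBTmin by 7 hours, elementwise", {
  expect_equal(dlmo_times(29), 22)     # CBTmin 05:00 (day 2) -> DLMO 22:00
  expect_equal(dlmo_times(numeric(0)), numeric(0))
  v <- c(29.5, 53.2, 77.1)
  expect_equal(dlmo_times(v + 1), dlmo_times(v) + 1)
})

test_that("average amplitude is a time-average of the state norm", {
  t <- seq(0, 48, by = 0.001)
  expect_equal(average_amplitude(t, rep(3, length(t)), rep(4, length(t))), 5)
  expect_equal(average_amplitude(t, cos(2 * pi * t / 24), sin(2 * pi * t / 24)), 1)
  # quadrature oracle: r(t) = 2 + sin(2 pi t / 24) over the last day
  x <- (2 + sin(2 * pi * t / 24))
  got <- average_amplitude(t, x, rep(0, length(t)), window = c(24, 48))
  expect_equal(got, 2, tolerance = 1e-6)
  expect_error(average_amplitude(t, x, x, window = c(40, 72)), "outside")
})
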