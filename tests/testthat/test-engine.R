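test_that("identical inputs give bit-identical trajectories", {
  sched <- build_equilibration_schedule(6, 3)
  a <- simulate(sched)
  b <- simulate(sched)
  expect_identical(a$x, b$x)
  expect_identical(a$H, b$H)
  expect_identical(a$episodes, b$episodes)
})

test_that("dark free-run reproduces the intrinsic period and forgets initial amplitude", {
  for (tau in c(23.8, 24.1, 24.4)) {
    cp <- circadian_params(tau_c = tau)
    res <- simulate(dark_schedule(30), cp, awake_params(),
                    initial = list(x = -1, xc = 0, n = 0, H = 1, asleep = FALSE))
    expect_lt(abs(mean(diff(res$cbt_min[-(1:2)])) - tau), 0.05)
  }
  # two starts converge to the same limit-cycle amplitude within 1%
  cp <- circadian_params()
  amp <- sapply(list(c(-0.3, 0.1), c(-1.5, 0.8)), function(s0) {
    r <- simulate(dark_schedule(30), cp, awake_params(),
                  initial = list(x = s0[1], xc = s0[2], n = 0, H = 1,
                                 asleep = FALSE))
    average_amplitude(r$time, r$x, r$xc)
  })
  expect_lt(abs(amp[1] - amp[2]) / amp[1], 0.01)
})

test_that("the coupled integrator agrees with an adaptive reference solver", {
  skip_if_not_installed("deSolve")
  cp <- circadian_params()
  lux <- 500
  rhs <- function(t, y, parms) {
    b <- light_drive(y[1], y[2], y[3], lux, cp)
    dxc <- oscillator_derivatives(y[1], y[2], b, cp)
    list(c(dxc, process_l_derivative(y[3], lux, cp)))
  }
  ref <- deSolve::ode(c(x = -1, xc = 0, n = 0), seq(0, 48, by = 0.01), rhs,
                      NULL, method = "ode45", atol = 1e-10, rtol = 1e-10)
  const <- light_schedule(data.frame(t_start = 0, t_end = 48,
                                     lux_start = lux, lux_end = lux))
  mine <- simulate(const, cp, awake_params(),
                   initial = list(x = -1, xc = 0, n = 0, H = 1, asleep = FALSE))
  expect_lt(max(abs(mine$x - ref[, "x"])), 1e-8)
  expect_lt(max(abs(mine$xc - ref[, "xc"])), 1e-8)
  expect_lt(max(abs(mine$n - ref[, "n"])), 1e-8)
})

test_that("halving the step changes the final CBTmin by less than 0.005 h", {
  a <- equilibrate(dt = 0.01)
  b <- equilibrate(dt = 0.005)
  expect_lt(abs(tail(a$result$cbt_min, 1) - tail(b$result$cbt_min, 1)), 0.005)
})

test_that("free-running sleep-wake cycles at the intrinsic period in darkness", {
  res <- simulate(dark_schedule(30), circadian_params(tau_c = 24.2),
                  sleep_params(wake_lux_threshold = Inf))
  ep <- res$episodes[res$episodes$onset > 120 & res$episodes$offset < 29 * 24, ]
  expect_true(all(abs(diff(ep$onset) - 24.2) < 0.1))
  expect_true(all(ep$duration > 6 & ep$duration < 10))
  # exactly one episode per circadian cycle (up to window-edge effects)
  expect_lt(abs(nrow(ep) - sum(res$cbt_min > 120 & res$cbt_min < 29 * 24)), 2)
})

test_that("equilibration is near-periodic, idempotent, and tracks lights-on", {
  eq6 <- equilibrate(lights_on = 6)
  expect_true(eq6$periodic)
  expect_true(eq6$entrained)
  # idempotence: re-equilibrating moves CBTmin clock time by under a minute
  eq6b <- equilibrate(lights_on = 6, initial = eq6$state)
  d <- abs(tail(eq6$result$cbt_min, 1) %% 24 - tail(eq6b$result$cbt_min, 1) %% 24)
  expect_lt(min(d, 24 - d) * 60, 1)
  # a 3 h later routine entrains the phase marker ~3 h later
  eq9 <- equilibrate(lights_on = 9)
  shift <- (tail(eq9$result$cbt_min, 1) - tail(eq6$result$cbt_min, 1)) %% 24
  expect_lt(abs(shift - 3), 1)
  # zero-day equilibration returns the initial state unchanged
  init <- default_initial_state()
  expect_identical(equilibrate(n_days = 0, initial = init)$state, init)
})

test_that("period and entrainment estimation match their definitions", {
  s24 <- seq(0, by = 24, length.out = 10)
  est <- estimate_period_and_entrainment(s24)
  expect_equal(est$period, 24)
  expect_equal(est$drift, 0)
  expect_true(est$entrained)
  s242 <- seq(0, by = 24.2, length.out = 10)
  est2 <- estimate_period_and_entrainment(s242)
  expect_equal(est2$drift, 0.2)
  expect_false(est2$entrained)
  # mean-difference estimator equals the least-squares slope on noiseless input
  slope <- unname(coef(lm(s242 ~ seq_along(s242)))[2])
  expect_equal(est2$period, slope)
  expect_error(estimate_period_and_entrainment(c(0, 24)), "at least 3")
})

test_that("sleep onsets localize to the event, not the grid", {
  # brute-force scan of the stored H/threshold/lux conditions finds the onset
  # within one integration step of the bisection-refined event time
  eq <- suppressWarnings(equilibrate(n_days = 8))
  res <- eq$result
  on <- res$episodes$onset[res$episodes$onset > 24 * 5][1]
  th <- sleep_thresholds(res$x, res$sparams)
  sched <- build_equilibration_schedule(6, 8)
  ok <- res$H >= th$upper & schedule_lux(sched, pmin(res$time, 24 * 8)) <= 0.5 &
    res$time > on - 6
  brute <- res$time[which(ok)[1]]
  expect_lt(abs(on - brute), 0.01 + 1e-9)
})

test_that("invalid integration requests are rejected", {
  sched <- dark_schedule(1)
  expect_error(simulate(sched, dt = 0.2), "dt")
  expect_error(simulate(sched, dt = 0.01, t_end = 10.005), "multiple of dt")
})
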