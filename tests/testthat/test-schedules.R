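test_that("reading-protocol schedule reproduces the prescribed lux sequence", {
  s90 <- build_chang_schedule(chang_protocol_spec(90, "ebook_first"))
  # day 1: 90 lux daytime, 30 lux eBook window, dark sleep window
  expect_equal(schedule_lux(s90, 12), 90)
  expect_equal(schedule_lux(s90, 20), 30)
  expect_equal(schedule_lux(s90, 23), 0)
  # book-first order puts 3 lux in the week-1 reading window
  sbf <- build_chang_schedule(chang_protocol_spec(90, "book_first"))
  expect_equal(schedule_lux(sbf, 20), 3)
  # second week swaps the reading condition (day 8 = t in [168, 192))
  expect_equal(schedule_lux(s90, 168 + 20), 3)
  expect_equal(schedule_lux(sbf, 168 + 20), 30)
  # CP days (6, 7, 13, 14) are dim all wake period
  expect_equal(schedule_lux(s90, 24 * 5 + 12), 3)
  expect_equal(schedule_lux(s90, 24 * 6 + 20), 3)
  # 500-lux variant changes only the daytime baseline
  s500 <- build_chang_schedule(chang_protocol_spec(500, "ebook_first"))
  expect_equal(schedule_lux(s500, 12), 500)
  expect_equal(schedule_lux(s500, 20), 30)
  tt <- seq(0, 24 * 14 - 0.025, by = 0.05)
  d <- which(abs(schedule_lux(s500, tt) - schedule_lux(s90, tt)) > 0)
  clock <- tt[d] %% 24
  day <- floor(tt[d] / 24) + 1
  expect_true(all(clock >= 6 & clock < 18))            # wake, non-reading hours
  expect_true(all(day %in% c(1:5, 8:12)))              # reading days only
})

test_that("protocol spec rejects invalid configurations", {
  expect_error(chang_protocol_spec(days_per_condition = 0), "at least 1")
  expect_error(chang_protocol_spec(ebook_lux = 3, book_lux = 3), "exceed")
  expect_error(chang_protocol_spec(reading_window = c(17, 23)), "wake period")
})

test_that("equilibration schedule is a 16:8 light-dark cycle with adjustable lights-on", {
  e6 <- build_equilibration_schedule(6, 30)
  expect_equal(schedule_lux(e6, 24 * 9 + 12), 1000)
  expect_equal(schedule_lux(e6, 24 * 9 + 23), 0)
  e9 <- build_equilibration_schedule(9, 30)
  expect_equal(schedule_lux(e9, 8), 0)
  expect_equal(schedule_lux(e9, 9.5), 1000)
  # the 09:00 light period crosses midnight and is truncated at the end
  expect_equal(schedule_lux(e9, 24.5), 1000)
  expect_equal(e9$total_days, 30L)
  expect_error(build_equilibration_schedule(6, 0), "empty")
})

test_that("pulse schedule has the nighttime floor, ramps and rectangular pulse", {
  p <- build_pulse_schedule(100, 7, 5000, 1, 20)
  expect_equal(schedule_lux(p, 3), 50)                # nighttime floor
  expect_equal(schedule_lux(p, 7), 75)                # 06:00-08:00 ramp midpoint
  expect_equal(schedule_lux(p, 13.5), 5000)           # pulse hour (13:00-14:00)
  expect_equal(schedule_lux(p, 21), 75)               # 20:00-22:00 down-ramp midpoint
  dark <- build_pulse_schedule(0, 0, 5000, 1, 20)
  expect_equal(schedule_lux(dark, 3), 0)              # full-darkness case
  expect_equal(schedule_lux(dark, 6.5), 5000)
  # caption ramp dialect moves the down-ramp to 18:00-20:00
  pc <- build_pulse_schedule(100, 7, ramp_dialect = "caption")
  expect_equal(schedule_lux(pc, 19), 75)
  expect_equal(schedule_lux(pc, 21), 50)
  expect_error(build_pulse_schedule(100, 7, pulse_duration_h = 12),
               "past the end of the day")
  expect_error(build_pulse_schedule(100, 15), "pulse_offset_h")
  expect_error(build_pulse_schedule(100, 7, pulse_lux = 50), "at least")
})

test_that("pulse adds exactly its lux-hours over the underlying day", {
  # trapezoid quadrature of (pulse day - no-pulse day) equals
  # duration * (pulse level - baseline at pulse time)
  withp <- build_pulse_schedule(100, 7, 5000, 1, 1)
  base <- splice_day <- build_pulse_schedule(100, 7, 100, 1, 1)  # degenerate pulse
  tt <- seq(0, 24, by = 0.001)
  d <- schedule_lux(withp, tt) - schedule_lux(base, tt)
  integral <- sum(diff(tt) * (d[-1] + d[-length(d)]) / 2)
  expect_equal(integral, 1 * (5000 - 100), tolerance = 1e-6)
})

test_that("every schedule evaluates finite and non-negative everywhere", {
  set.seed(42)
  scheds <- list(build_chang_schedule(chang_protocol_spec(90)),
                 build_equilibration_schedule(7, 30),
                 build_pulse_schedule(250, 9))
  for (s in scheds) {
    tt <- runif(10000, 0, 24 * s$total_days)
    v <- schedule_lux(s, tt)
    expect_true(all(is.finite(v)))
    expect_true(all(v >= 0))
  }
  expect_error(schedule_lux(scheds[[2]], 24 * 31), "outside")
})

test_that("circadian light input is zeroed during sleep", {
  s <- build_chang_schedule(chang_protocol_spec(90))
  expect_equal(lux_for_circadian_input(s, 12, asleep = TRUE), 0)
  expect_equal(lux_for_circadian_input(s, 12, asleep = FALSE), 90)
  # linear interpolation inside a ramp segment
  p <- build_pulse_schedule(100, 7)
  expect_equal(lux_for_circadian_input(p, 6.5, FALSE), 50 + 0.25 * (100 - 50))
})

test_that("schedules round-trip through CSV and JSON", {
  s <- build_pulse_schedule(100, 7)
  fc <- tempfile(fileext = ".csv"); fj <- tempfile(fileext = ".json")
  write_schedule_csv(s, fc)
  s2 <- read_schedule_csv(fc, label = s$label)
  expect_equal(s2$segments, s$segments)
  write_schedule_json(s, fj)
  s3 <- read_schedule_json(fj)
  expect_equal(s3$segments, s$segments, tolerance = 1e-12)
  expect_equal(s3$label, s$label)
  unlink(c(fc, fj))
})

test_that("malformed segment tables are rejected", {
  expect_error(light_schedule(data.frame(t_start = 0, t_end = 23,
                                         lux_start = 0, lux_end = 0)),
               "whole number of days")
  expect_error(light_schedule(data.frame(t_start = c(0, 10), t_end = c(12, 24),
                                         lux_start = 0, lux_end = 0)),
               "gaps or overlaps")
  expect_error(light_schedule(data.frame(t_start = 0, t_end = 24,
                                         lux_start = -5, lux_end = 0)),
               "non-negative")
})
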