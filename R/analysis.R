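# Clock-time helpers ---------------------------------------------------------

clock_of <- function(t) t %% 24

# Difference later - earlier between two clock times, wrapped to (-12, 12].
clock_diff_h <- function(later, earlier) {
  d <- (later - earlier) %% 24
  ifelse(d > 12, d - 24, d)
}

# First CBTmin falling inside day `day` (1-based, day d = [24(d-1), 24d)).
cbt_on_day <- function(result, day) {
  w0 <- 24 * (day - 1); w1 <- 24 * day
  hit <- result$cbt_min[result$cbt_min >= w0 & result$cbt_min < w1]
  if (length(hit) == 0) stop("no CBTmin marker on day ", day)
  hit[1]
}

#' Sleep onset latency per protocol night
#'
#' SOL is the time from the scheduled bedtime (lights-off, when the schedule
#' drops to or below the wake-lux threshold at `bedtime_clock`) to the model's
#' sleep onset, in minutes. Nights with no sleep onset before the next
#' lights-on are reported as `NA` (missing), never as zero.
#'
#' @param result a [simulate()] result.
#' @param nights integer day indices (1-based) of the nights to score.
#' @param bedtime_clock scheduled bedtime clock hour (default 22).
#' @param wake_clock next-morning lights-on clock hour bounding the night.
#' @return data.frame with columns `night`, `sol_min`, `onset`.
#' @export
sleep_onset_latency <- function(result, nights, bedtime_clock = 22,
                                wake_clock = 6) {
  ep <- result$episodes
  rows <- lapply(nights, function(d) {
    bed <- 24 * (d - 1) + bedtime_clock
    night_end <- bed + (24 - bedtime_clock) + wake_clock
    on <- ep$onset[ep$onset >= bed - 1e-6 & ep$onset < night_end]
    sol <- if (length(on) == 0) NA_real_ else (on[1] - bed) * 60
    data.frame(night = d, sol_min = sol,
               onset = if (length(on) == 0) NA_real_ else on[1])
  })
  do.call(rbind, rows)
}

#' Phase shift between two constant-posture days
#'
#' The shift is the wrapped clock-time difference of the CBTmin markers on the
#' two CP days (later day minus earlier day), in minutes; positive values are
#' delays. A missing marker on either day is an error.
#'
#' @param result a [simulate()] result.
#' @param cp_day_pair integer vector `c(earlier_day, later_day)` (1-based).
#' @return shift in minutes (positive = delay).
#' @export
phase_shift <- function(result, cp_day_pair = c(7, 13)) {
  c1 <- clock_of(cbt_on_day(result, cp_day_pair[1]))
  c2 <- clock_of(cbt_on_day(result, cp_day_pair[2]))
  clock_diff_h(c2, c1) * 60
}

#' eBook-attributable phase shift for a two-condition run
#'
#' Compares CBTmin clock time at the end of the eBook week against the end of
#' the Book week within one two-condition run, using the day-7 and day-13
#' constant-posture read-outs. Positive values mean the eBook left the clock
#' later than the Book (a delay attributed to the eBook).
#'
#' @param result a [simulate()] result of a [build_chang_schedule()] run.
#' @param order `"ebook_first"` or `"book_first"` (the order simulated).
#' @param cp_days the two CP read-out days (default `c(7, 13)`).
#' @return shift in minutes (positive = eBook-attributable delay).
#' @export
condition_phase_difference <- function(result,
                                       order = c("ebook_first", "book_first"),
                                       cp_days = c(7, 13)) {
  order <- match.arg(order)
  ps <- phase_shift(result, cp_days)  # week-2 minus week-1, minutes
  if (order == "ebook_first") -ps else ps
}

#' Bedtime and total sleep time for one day
#'
#' Bedtime is the onset clock time of the day's main (longest) sleep episode;
#' total sleep time sums the full durations of all episodes whose onset falls
#' in the day (an episode split across midnight is attributed to its onset
#' day). A day without sleep returns `NA`s.
#'
#' @param result a [simulate()] result.
#' @param day 1-based day index.
#' @return list with `bedtime_clock` (hours) and `tst_min` (minutes).
#' @export
bedtime_and_tst <- function(result, day) {
  w0 <- 24 * (day - 1); w1 <- 24 * day
  ep <- result$episodes
  sel <- ep[ep$onset >= w0 & ep$onset < w1, ]
  if (nrow(sel) == 0) {
    return(list(bedtime_clock = NA_real_, tst_min = NA_real_))
  }
  dur <- sel$offset - sel$onset
  list(bedtime_clock = clock_of(sel$onset[which.max(dur)]),
       tst_min = sum(dur) * 60)
}

#' Average-amplitude map over baseline light and pulse timing
#'
#' Simulates a 20-day baseline-plus-pulse schedule for every combination of
#' baseline level and pulse offset, and returns the circadian amplitude
#' averaged over the last simulated day. Sleep timing is endogenous in these
#' runs (no light forcing). Failed cells are `NA`.
#'
#' @param baselines numeric vector of baseline lux levels (0 to 1000).
#' @param offsets numeric vector of pulse offsets, hours after waking (0-14).
#' @param cparams,sparams model parameters (light forcing is disabled
#'   internally regardless of `sparams$wake_lux_threshold`).
#' @param pulse_lux,pulse_duration_h,n_days pulse-schedule settings.
#' @param dt integration step (hours).
#' @return data.frame with columns `baseline_lux`, `pulse_offset_h`,
#'   `amplitude`.
#' @export
amplitude_heatmap <- function(baselines, offsets,
                              cparams = circadian_params(),
                              sparams = sleep_params(),
                              pulse_lux = 5000, pulse_duration_h = 1,
                              n_days = 20, dt = 0.01) {
  sp <- sparams
  sp$wake_lux_threshold <- Inf
  grid <- expand.grid(baseline_lux = baselines, pulse_offset_h = offsets,
                      KEEP.OUT.ATTRS = FALSE)
  init <- default_initial_state(cparams, sp, cbt_min_clock = 3, dt = dt)
  grid$amplitude <- vapply(seq_len(nrow(grid)), function(i) {
    tryCatch({
      sched <- build_pulse_schedule(grid$baseline_lux[i],
                                    grid$pulse_offset_h[i],
                                    pulse_lux, pulse_duration_h, n_days)
      res <- simulate(sched, cparams, sp, initial = init, dt = dt)
      average_amplitude(res$time, res$x, res$xc)
    }, error = function(e) NA_real_)
  }, numeric(1))
  grid
}

#' Run one baseline-plus-pulse simulation
#'
#' Convenience wrapper: builds the pulse schedule, disables light forcing
#' (sleep timing is endogenous under the 50-lux nighttime floor) and simulates
#' `n_days` from the standard initial state, positioned at the model's
#' entrained phase on bright regular schedules (first CBTmin near 03:00) so
#' that the final analysed day represents near-steady behavior. The run is
#' extended half a day past `n_days` so the final night's sleep episode
#' completes and can be attributed to the last analysed day.
#'
#' @inheritParams amplitude_heatmap
#' @param baseline_lux baseline plateau level.
#' @param pulse_offset_h pulse start, hours after the 06:00 waking reference.
#' @return a [simulate()] result.
#' @export
run_pulse_simulation <- function(baseline_lux, pulse_offset_h,
                                 cparams = circadian_params(),
                                 sparams = sleep_params(),
                                 pulse_lux = 5000, pulse_duration_h = 1,
                                 n_days = 20, dt = 0.01) {
  sp <- sparams
  sp$wake_lux_threshold <- Inf
  sched <- build_pulse_schedule(baseline_lux, pulse_offset_h, pulse_lux,
                                pulse_duration_h, n_days + 1)
  init <- default_initial_state(cparams, sp, cbt_min_clock = 3, dt = dt)
  simulate(sched, cparams, sp, initial = init, dt = dt,
           t_end = 24 * n_days + 12)
}

#' Double-plotted actogram
#'
#' Renders the classic day-by-48-hour raster: row `d` shows days `d` and
#' `d + 1` side by side, colored by schedule illuminance, with sleep drawn as
#' a gray overlay. Useful for reading entrainment (vertically aligned sleep
#' bands) versus free-running drift.
#'
#' @param result a [simulate()] result.
#' @param schedule the [light_schedule()] that produced it.
#' @param bin_h raster bin width in hours.
#' @return a ggplot object.
#' @export
make_actogram <- function(result, schedule, bin_h = 0.25) {
  n_days <- schedule$total_days
  if (n_days < 2) stop("actogram needs at least 2 days")
  rows <- lapply(seq_len(n_days - 1), function(d) {
    tt <- seq(24 * (d - 1), 24 * (d + 1) - bin_h, by = bin_h)
    mid <- tt + bin_h / 2
    idx <- pmin(findInterval(mid, result$time), length(result$time))
    data.frame(day = d, hour = tt - 24 * (d - 1),
               lux = schedule_lux(schedule, pmin(mid, 24 * n_days)),
               asleep = result$asleep[idx])
  })
  df <- do.call(rbind, rows)
  ggplot2::ggplot(df, ggplot2::aes(x = hour + bin_h / 2, y = day)) +
    ggplot2::geom_tile(ggplot2::aes(fill = log10(lux + 1))) +
    ggplot2::geom_tile(data = df[df$asleep, ], fill = "gray40") +
    ggplot2::scale_fill_viridis_c(option = "cividis", name = "log10(lux+1)") +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_x_continuous(breaks = seq(0, 48, 12)) +
    ggplot2::labs(x = "time of day (double plotted, h)", y = "day",
                  title = result$schedule_label) +
    ggplot2::theme_minimal()
}

#' Run the two-week reading protocol for one parameter set
#'
#' Equilibrates on the regular 1000-lux schedule and then simulates the
#' two-week eBook/Book protocol, returning the per-night sleep onset
#' latencies for both conditions and the eBook-attributable phase shift.
#'
#' @param cparams,sparams model parameters.
#' @param baseline_lux protocol daytime level (90 or 500).
#' @param order `"ebook_first"` or `"book_first"`.
#' @param lights_on pre-study equilibration lights-on hour (default 6).
#' @param equilibration_days days of equilibration (default 30).
#' @param dt integration step (hours).
#' @return list with `sol` (data.frame: night, condition, sol_min),
#'   `ebook_shift_min`, and `result` (the protocol [simulate()] output).
#' @export
run_chang_protocol <- function(cparams = circadian_params(),
                               sparams = sleep_params(),
                               baseline_lux = 90,
                               order = c("ebook_first", "book_first"),
                               lights_on = 6, equilibration_days = 30,
                               dt = 0.01) {
  order <- match.arg(order)
  spec <- chang_protocol_spec(baseline_lux = baseline_lux, order = order)
  sched <- build_chang_schedule(spec)
  init <- equilibrate(cparams, sparams, lights_on = lights_on,
                      n_days = equilibration_days, dt = dt)$state
  res <- simulate(sched, cparams, sparams, initial = init, dt = dt)
  n_rd <- spec$days_per_condition
  week2_start <- n_rd + spec$cp_days_per_condition
  sol1 <- sleep_onset_latency(res, seq_len(n_rd))
  sol2 <- sleep_onset_latency(res, week2_start + seq_len(n_rd))
  cond1 <- if (order == "ebook_first") "ebook" else "book"
  cond2 <- if (order == "ebook_first") "book" else "ebook"
  sol <- rbind(cbind(sol1, condition = cond1),
               cbind(sol2, condition = cond2))
  list(sol = sol[, c("night", "condition", "sol_min")],
       ebook_shift_min = condition_phase_difference(res, order),
       result = res)
}

#' Ensemble run of the reading protocol
#'
#' Runs [run_chang_protocol()] for every row of a parameter table (columns
#' `mu`, `delta`, `chi` and optionally `p`, `kappa`, `tau_c`; extra columns
#' are ignored) and both requested orders, and returns a long metrics table.
#'
#' @param points data.frame of parameter sets (one row per set).
#' @param baseline_lux protocol daytime level.
#' @param orders character vector of condition orders to run.
#' @param lights_on,equilibration_days,dt passed to [run_chang_protocol()].
#' @return data.frame with one row per (set, order, condition, night):
#'   columns `set_id`, `order`, `condition`, `night`, `sol_min`,
#'   `ebook_shift_min`, `baseline_lux`.
#' @export
run_chang_ensemble <- function(points, baseline_lux = 90,
                               orders = c("ebook_first", "book_first"),
                               lights_on = 6, equilibration_days = 30,
                               dt = 0.01) {
  has_circ <- all(c("p", "kappa", "tau_c") %in% names(points))
  ids <- if ("set_id" %in% names(points)) points$set_id else seq_len(nrow(points))
  out <- list()
  for (i in seq_len(nrow(points))) {
    row <- points[i, ]
    cp <- if (has_circ) {
      circadian_params(p = row$p, kappa = row$kappa, tau_c = row$tau_c)
    } else circadian_params()
    sp <- sleep_params(mu = row$mu, delta = row$delta, chi = row$chi)
    for (ord in orders) {
      run <- run_chang_protocol(cp, sp, baseline_lux = baseline_lux,
                                order = ord, lights_on = lights_on,
                                equilibration_days = equilibration_days,
                                dt = dt)
      tbl <- run$sol
      tbl$set_id <- ids[i]
      tbl$order <- ord
      tbl$ebook_shift_min <- run$ebook_shift_min
      tbl$baseline_lux <- baseline_lux
      out[[length(out) + 1L]] <- tbl
    }
  }
  do.call(rbind, out)
}

#' Summarize an ensemble metrics table
#'
#' Aggregates a [run_chang_ensemble()] table: per condition (and order) means,
#' medians and standard deviations of sleep onset latency, the mean
#' eBook-minus-Book SOL difference `delta_sol_min`, and the per-order medians
#' of the eBook-attributable phase shift.
#'
#' @param metrics a [run_chang_ensemble()] data.frame.
#' @return list with `sol_by_condition`, `delta_sol_min`,
#'   `shift_by_order` (data.frame: order, median/mean shift in minutes) and
#'   `n_sets`.
#' @export
summarize_ensemble <- function(metrics) {
  stopifnot(nrow(metrics) > 0)
  agg <- function(x) c(mean = mean(x, na.rm = TRUE),
                       median = stats::median(x, na.rm = TRUE),
                       sd = stats::sd(x, na.rm = TRUE))
  sol_by <- do.call(rbind, lapply(split(metrics, metrics$condition), function(d) {
    data.frame(condition = d$condition[1], t(agg(d$sol_min)))
  }))
  rownames(sol_by) <- NULL
  delta <- mean(metrics$sol_min[metrics$condition == "ebook"], na.rm = TRUE) -
    mean(metrics$sol_min[metrics$condition == "book"], na.rm = TRUE)
  per_run <- unique(metrics[, c("set_id", "order", "ebook_shift_min")])
  shift_by <- do.call(rbind, lapply(split(per_run, per_run$order), function(d) {
    data.frame(order = d$order[1],
               median_shift_min = stats::median(d$ebook_shift_min),
               mean_shift_min = mean(d$ebook_shift_min),
               iqr_shift_min = stats::IQR(d$ebook_shift_min))
  }))
  rownames(shift_by) <- NULL
  list(sol_by_condition = sol_by, delta_sol_min = delta,
       shift_by_order = shift_by, n_sets = length(unique(metrics$set_id)))
}
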