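#' Piecewise-linear light schedules
#'
#' A `light_schedule` is a deterministic lux-vs-time forcing function covering
#' an integer number of 24 h days. It is stored as an ordered set of segments
#' `(t_start, t_end, lux_start, lux_end)`, in hours since the start of the
#' simulation, with linear interpolation inside each segment. Segments must
#' tile `[0, 24 * total_days]` with no gaps or overlaps and illuminance must be
#' non-negative everywhere.
#'
#' @param segments data.frame with numeric columns `t_start`, `t_end`,
#'   `lux_start`, `lux_end`.
#' @param label free-text description carried along with the schedule.
#' @return An object of class `light_schedule` with elements `segments`,
#'   `total_days` and `label`.
#' @export
light_schedule <- function(segments, label = "") {
  stopifnot(is.data.frame(segments))
  need <- c("t_start", "t_end", "lux_start", "lux_end")
  if (!all(need %in% names(segments))) {
    stop("segments must have columns t_start, t_end, lux_start, lux_end")
  }
  segments <- segments[order(segments$t_start), need, drop = FALSE]
  rownames(segments) <- NULL
  if (nrow(segments) == 0L) stop("schedule must contain at least one segment")
  if (any(!is.finite(as.matrix(segments)))) stop("segments must be finite")
  if (any(segments$lux_start < 0) || any(segments$lux_end < 0)) {
    stop("illuminance must be non-negative")
  }
  if (any(segments$t_end <= segments$t_start)) {
    stop("each segment must have t_end > t_start")
  }
  tol <- 1e-9
  if (abs(segments$t_start[1]) > tol) stop("schedule must start at t = 0")
  gaps <- segments$t_start[-1] - segments$t_end[-nrow(segments)]
  if (any(abs(gaps) > tol)) stop("segments must tile time with no gaps or overlaps")
  t_end <- segments$t_end[nrow(segments)]
  total_days <- t_end / 24
  if (abs(total_days - round(total_days)) > tol) {
    stop("schedule must cover a whole number of days")
  }
  structure(
    list(segments = segments, total_days = as.integer(round(total_days)),
         label = label),
    class = "light_schedule"
  )
}

#' @export
print.light_schedule <- function(x, ...) {
  cat(sprintf("<light_schedule> %s: %d days, %d segments, lux range [%g, %g]\n",
              x$label, x$total_days, nrow(x$segments),
              min(x$segments$lux_start, x$segments$lux_end),
              max(x$segments$lux_start, x$segments$lux_end)))
  invisible(x)
}

#' Evaluate a light schedule
#'
#' Linear interpolation inside segments; right-continuous at segment
#' boundaries (the value at an instantaneous step change is the value of the
#' segment that starts there). The very last instant of the schedule takes the
#' final segment's end value.
#'
#' @param schedule a [light_schedule()].
#' @param t numeric vector of times in hours since schedule start.
#' @return numeric vector of lux values.
#' @export
schedule_lux <- function(schedule, t) {
  stopifnot(inherits(schedule, "light_schedule"))
  seg <- schedule$segments
  t_total <- 24 * schedule$total_days
  if (any(t < -1e-9 | t > t_total + 1e-9)) {
    stop("t outside schedule range [0, ", t_total, "]")
  }
  t <- pmin(pmax(t, 0), t_total)
  # right-continuous: index of segment with t_start <= t < t_end
  i <- findInterval(t, seg$t_start, rightmost.closed = FALSE)
  i <- pmin(pmax(i, 1L), nrow(seg))
  frac <- (t - seg$t_start[i]) / (seg$t_end[i] - seg$t_start[i])
  pmax(seg$lux_start[i] + frac * (seg$lux_end[i] - seg$lux_start[i]), 0)
}

#' Light input seen by the circadian pacemaker
#'
#' During sleep the eyes are closed and photic input to the oscillator is
#' zero; while awake the environmental schedule value is used.
#'
#' @inheritParams schedule_lux
#' @param asleep logical vector (recycled against `t`).
#' @return numeric vector of lux values.
#' @export
lux_for_circadian_input <- function(schedule, t, asleep) {
  out <- schedule_lux(schedule, t)
  out[rep_len(asleep, length(out))] <- 0
  out
}

# Build a constant-lux segment row.
seg_row <- function(t0, t1, l0, l1 = l0) {
  data.frame(t_start = t0, t_end = t1, lux_start = l0, lux_end = l1)
}

#' Specification of the two-week eBook/Book reading protocol
#'
#' Encodes the laboratory protocol: dim-room daytime light, a four-hour
#' evening reading window in which the light source is either an eBook screen
#' (30 lux) or a paper book under dim room light (3 lux), a dark 22:00-06:00
#' sleep opportunity, five reading days per condition, and two constant-
#' posture (CP) assessment days in very dim light at the end of each
#' condition week.
#'
#' @param baseline_lux daytime illuminance outside the reading window
#'   (90 lux in the original laboratory study; 500 lux for the bright-day
#'   variant).
#' @param order `"ebook_first"` or `"book_first"`.
#' @param days_per_condition number of reading days per condition (default 5).
#' @param reading_window clock-hour interval `c(start, end)` of the evening
#'   reading period, inside the wake period.
#' @param ebook_lux,book_lux illuminance during the reading window in the two
#'   conditions; `ebook_lux` must exceed `book_lux`.
#' @param sleep_window clock-hour interval of the dark sleep opportunity
#'   (crosses midnight; default 22:00-06:00).
#' @param cp_lux illuminance of the constant-posture assessment days. The
#'   original protocol does not state this value; dim light (3 lux) is used so
#'   that the melatonin-based phase assessment convention is respected.
#' @return An object of class `protocol_spec`.
#' @export
chang_protocol_spec <- function(baseline_lux = 90,
                                order = c("ebook_first", "book_first"),
                                days_per_condition = 5,
                                reading_window = c(18, 22),
                                ebook_lux = 30, book_lux = 3,
                                sleep_window = c(22, 6),
                                cp_lux = 3) {
  order <- match.arg(order)
  if (days_per_condition < 1) stop("days_per_condition must be at least 1")
  if (baseline_lux < 0 || ebook_lux < 0 || book_lux < 0 || cp_lux < 0) {
    stop("illuminances must be non-negative")
  }
  if (ebook_lux <= book_lux) stop("ebook_lux must exceed book_lux")
  wake_start <- sleep_window[2]
  wake_end <- sleep_window[1]
  if (!(reading_window[1] >= wake_start && reading_window[2] <= wake_end &&
        reading_window[1] < reading_window[2])) {
    stop("reading window must lie inside the scheduled wake period")
  }
  structure(
    list(baseline_lux = baseline_lux, order = order,
         days_per_condition = days_per_condition,
         reading_window = reading_window,
         ebook_lux = ebook_lux, book_lux = book_lux,
         sleep_window = sleep_window, cp_lux = cp_lux,
         cp_days_per_condition = 2),
    class = "protocol_spec"
  )
}

#' Build the two-week eBook/Book light schedule
#'
#' Lays out two condition weeks. With the defaults each week has five reading
#' days followed by two constant-posture days: condition 1 occupies days 1-7
#' and condition 2 days 8-14, matching the day-7 and day-13 phase read-out
#' convention used by the analysis functions. On reading days the wake period
#' runs at `baseline_lux` outside the reading window and at the condition's
#' reading lux inside it; on CP days the whole wake period is at `cp_lux`; the
#' sleep window is dark.
#'
#' @param spec a [chang_protocol_spec()].
#' @return A [light_schedule()] covering both weeks.
#' @export
build_chang_schedule <- function(spec) {
  stopifnot(inherits(spec, "protocol_spec"))
  first <- if (spec$order == "ebook_first") spec$ebook_lux else spec$book_lux
  second <- if (spec$order == "ebook_first") spec$book_lux else spec$ebook_lux
  n_rd <- spec$days_per_condition
  n_cp <- spec$cp_days_per_condition
  days_per_week <- n_rd + n_cp
  day_plan <- c(rep("read1", n_rd), rep("cp", n_cp),
                rep("read2", n_rd), rep("cp", n_cp))
  ws <- spec$sleep_window[2]   # wake start (06:00)
  we <- spec$sleep_window[1]   # wake end / lights off (22:00)
  rs <- spec$reading_window[1]
  re <- spec$reading_window[2]
  segs <- vector("list", length(day_plan))
  for (d in seq_along(day_plan)) {
    o <- 24 * (d - 1)
    kind <- day_plan[d]
    if (kind == "cp") {
      day <- rbind(seg_row(o, o + ws, 0),
                   seg_row(o + ws, o + we, spec$cp_lux),
                   seg_row(o + we, o + 24, 0))
    } else {
      rlux <- if (kind == "read1") first else second
      day <- rbind(seg_row(o, o + ws, 0),
                   seg_row(o + ws, o + rs, spec$baseline_lux),
                   seg_row(o + rs, o + re, rlux),
                   if (re < we) seg_row(o + re, o + we, spec$baseline_lux),
                   seg_row(o + we, o + 24, 0))
    }
    segs[[d]] <- day
  }
  light_schedule(do.call(rbind, segs),
                 label = sprintf("chang_%glux_%s", spec$baseline_lux, spec$order))
}

#' Build a regular bright-light equilibration schedule
#'
#' A 16 h : 8 h light-dark cycle at constant illuminance, used to entrain a
#' parameter set to a habitual routine before a protocol begins. Light runs
#' from `lights_on` for `light_hours` each day; periods that would extend past
#' the end of the final day are truncated at the schedule end.
#'
#' @param lights_on clock hour of lights on (e.g. 6 for 06:00). Values from 5
#'   to 9 emulate different habitual pre-study routines.
#' @param n_days number of days (default 30).
#' @param lux illuminance during the light period (default 1000).
#' @param light_hours daily light duration in hours (default 16).
#' @return A [light_schedule()].
#' @export
build_equilibration_schedule <- function(lights_on = 6, n_days = 30,
                                         lux = 1000, light_hours = 16) {
  if (n_days < 1) stop("n_days must be at least 1 (empty schedule)")
  if (lights_on < 0 || lights_on >= 24) stop("lights_on must be a clock hour in [0, 24)")
  t_total <- 24 * n_days
  on <- lights_on + 24 * (seq_len(n_days) - 1)
  off <- pmin(on + light_hours, t_total)
  pieces <- list()
  cursor <- 0
  for (i in seq_len(n_days)) {
    if (on[i] > cursor) pieces[[length(pieces) + 1L]] <- seg_row(cursor, on[i], 0)
    if (off[i] > on[i]) pieces[[length(pieces) + 1L]] <- seg_row(on[i], off[i], lux)
    cursor <- off[i]
  }
  if (cursor < t_total) pieces[[length(pieces) + 1L]] <- seg_row(cursor, t_total, 0)
  light_schedule(do.call(rbind, pieces),
                 label = sprintf("equilibration_%gh_on_%glux_%dd", lights_on, lux, n_days))
}

# Replace the part of a one-day segment table inside [t0, t1] with a constant
# level, splitting the segments that straddle the boundaries.
splice_constant <- function(day_segs, t0, t1, lux) {
  out <- list()
  for (i in seq_len(nrow(day_segs))) {
    s <- day_segs[i, ]
    interp <- function(t) {
      s$lux_start + (t - s$t_start) / (s$t_end - s$t_start) * (s$lux_end - s$lux_start)
    }
    if (s$t_end <= t0 || s$t_start >= t1) {
      out[[length(out) + 1L]] <- s
      next
    }
    if (s$t_start < t0) {
      out[[length(out) + 1L]] <- seg_row(s$t_start, t0, s$lux_start, interp(t0))
    }
    if (s$t_end > t1) {
      out[[length(out) + 1L]] <- seg_row(t1, s$t_end, interp(t1), s$lux_end)
    }
  }
  out[[length(out) + 1L]] <- seg_row(t0, t1, lux)
  do.call(rbind, out)
}

#' Build a baseline-plus-pulse light schedule
#'
#' Each day carries a nighttime floor before 06:00 and after 22:00, a linear
#' ramp up to the baseline level, a flat baseline plateau, a linear ramp back
#' down, and a rectangular bright pulse placed a fixed number of hours after
#' the 06:00 waking reference time. The nighttime floor is 50 lux except in
#' the full-darkness case (`baseline_lux = 0`), where it is 0.
#'
#' Two ramp conventions are available. The default `"methods"` dialect ramps
#' up 06:00-08:00 and down 20:00-22:00 between the nighttime and baseline
#' values; the `"caption"` dialect instead ramps down 18:00-20:00.
#'
#' @param baseline_lux daytime plateau illuminance (>= 0).
#' @param pulse_offset_h pulse start, hours after the 06:00 waking reference
#'   (0 to 14).
#' @param pulse_lux pulse illuminance (default 5000); must be at least
#'   `baseline_lux`.
#' @param pulse_duration_h pulse length in hours (default 1). A pulse
#'   extending past midnight is an error (no wrap-around).
#' @param n_days number of days (default 20).
#' @param ramp_dialect `"methods"` (default) or `"caption"`.
#' @return A [light_schedule()].
#' @export
build_pulse_schedule <- function(baseline_lux, pulse_offset_h,
                                 pulse_lux = 5000, pulse_duration_h = 1,
                                 n_days = 20,
                                 ramp_dialect = c("methods", "caption")) {
  ramp_dialect <- match.arg(ramp_dialect)
  if (baseline_lux < 0) stop("baseline_lux must be non-negative")
  if (pulse_offset_h < 0 || pulse_offset_h > 14) {
    stop("pulse_offset_h must lie in [0, 14] hours after waking")
  }
  if (pulse_lux < baseline_lux) stop("pulse_lux must be at least baseline_lux")
  if (n_days < 1) stop("n_days must be at least 1")
  night <- if (baseline_lux == 0) 0 else 50
  p0 <- 6 + pulse_offset_h
  p1 <- p0 + pulse_duration_h
  if (p1 > 24) stop("pulse extends past the end of the day; wrap is not performed")
  down <- if (ramp_dialect == "methods") c(20, 22) else c(18, 20)
  day <- rbind(
    seg_row(0, 6, night),
    seg_row(6, 8, night, baseline_lux),
    seg_row(8, down[1], baseline_lux),
    seg_row(down[1], down[2], baseline_lux, night),
    seg_row(down[2], 24, night)
  )
  day <- splice_constant(day, p0, p1, pulse_lux)
  day <- day[order(day$t_start), ]
  segs <- do.call(rbind, lapply(seq_len(n_days) - 1L, function(d) {
    s <- day
    s$t_start <- s$t_start + 24 * d
    s$t_end <- s$t_end + 24 * d
    s
  }))
  light_schedule(segs, label = sprintf("pulse_base%g_off%gh_%glux",
                                       baseline_lux, pulse_offset_h, pulse_lux))
}

#' Schedule serialization
#'
#' Schedules round-trip losslessly through CSV (segment table) and JSON
#' (segment table plus label).
#'
#' @param schedule a [light_schedule()].
#' @param path file path.
#' @return `write_*` return `path` invisibly; `read_*` return a
#'   [light_schedule()].
#' @name schedule_io
NULL

#' @rdname schedule_io
#' @export
write_schedule_csv <- function(schedule, path) {
  utils::write.csv(schedule$segments, path, row.names = FALSE)
  invisible(path)
}

#' @rdname schedule_io
#' @export
read_schedule_csv <- function(path, label = "") {
  light_schedule(utils::read.csv(path), label = label)
}

#' @rdname schedule_io
#' @param label label for schedules read from CSV (JSON stores its own).
#' @export
write_schedule_json <- function(schedule, path) {
  jsonlite::write_json(
    list(label = schedule$label, segments = schedule$segments),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname schedule_io
#' @export
read_schedule_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  light_schedule(as.data.frame(x$segments), label = x$label)
}
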