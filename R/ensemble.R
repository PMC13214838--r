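#' Parameter grids for the ensemble simulations
#'
#' Both grids are 5 x 5 x 5 = 125 evenly spaced points with inclusive
#' endpoints, the unique factorization of the reported 125 sets over three
#' swept axes.
#'
#' `make_sleep_grid()` spans the sleep phenotype: mean upper threshold
#' `mu` in \[17.5, 19.5\], threshold gap `delta` in \[5, 9\] and sleep-phase
#' decay constant `chi` in \[7, 11\] hours.
#'
#' `make_circadian_grid()` spans the circadian phenotype: photic sensitivity
#' `p` in \[0.5, 0.7\], drive shape `kappa` in \[0.4, 0.7\] and intrinsic
#' period `tau_c` in \[23.8, 24.4\] h; every point carries the fixed sleep
#' parameters `mu = 19.0`, `delta = 6.0`, `chi = 11.0`.
#'
#' @param n_per_axis points per axis (default 5).
#' @return An object of class `parameter_grid`: list with `points`
#'   (data.frame, one row per set), `kind` (`"sleep"` or `"circadian"`) and
#'   `axes` (named list of axis vectors).
#' @name parameter_grids
NULL

#' @rdname parameter_grids
#' @export
make_sleep_grid <- function(n_per_axis = 5) {
  axes <- list(mu = seq(17.5, 19.5, length.out = n_per_axis),
               delta = seq(5, 9, length.out = n_per_axis),
               chi = seq(7, 11, length.out = n_per_axis))
  points <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  points$set_id <- seq_len(nrow(points))
  structure(list(points = points, kind = "sleep", axes = axes),
            class = "parameter_grid")
}

#' @rdname parameter_grids
#' @export
make_circadian_grid <- function(n_per_axis = 5) {
  axes <- list(p = seq(0.5, 0.7, length.out = n_per_axis),
               kappa = seq(0.4, 0.7, length.out = n_per_axis),
               tau_c = seq(23.8, 24.4, length.out = n_per_axis))
  points <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  points$mu <- 19.0
  points$delta <- 6.0
  points$chi <- 11.0
  points$set_id <- seq_len(nrow(points))
  structure(list(points = points, kind = "circadian", axes = axes),
            class = "parameter_grid")
}

# Parameter objects for one grid row.
grid_point_params <- function(grid, i, wake_lux_threshold = 0.5) {
  row <- grid$points[i, ]
  if (grid$kind == "sleep") {
    cp <- circadian_params()
    sp <- sleep_params(mu = row$mu, delta = row$delta, chi = row$chi,
                       wake_lux_threshold = wake_lux_threshold)
  } else {
    cp <- circadian_params(p = row$p, kappa = row$kappa, tau_c = row$tau_c)
    sp <- sleep_params(mu = row$mu, delta = row$delta, chi = row$chi,
                       wake_lux_threshold = wake_lux_threshold)
  }
  list(cparams = cp, sparams = sp)
}

#' Run a parameter sweep over a schedule
#'
#' Each grid point is (optionally) equilibrated on the regular bright-light
#' schedule and then simulated on `schedule`. Results keep grid order and are
#' independent of execution order. Per-point failures are captured, not fatal.
#'
#' @param grid a [make_sleep_grid()] / [make_circadian_grid()] object.
#' @param schedule a [light_schedule()] to simulate after equilibration.
#' @param equilibration_days days of 1000-lux 16:8 equilibration before the
#'   protocol (0 to skip).
#' @param lights_on equilibration lights-on clock hour.
#' @param dt integration step (hours).
#' @param wake_lux_threshold light-forcing threshold passed to every point.
#' @param reduce optional `function(result, i)` applied to each
#'   [simulate()] result; when given, only its value is retained (keeps
#'   memory flat on large sweeps).
#' @return list of per-point results (or reduced values); failed points hold
#'   the condition object.
#' @export
run_sweep <- function(grid, schedule, equilibration_days = 30, lights_on = 6,
                      dt = 0.01, wake_lux_threshold = 0.5, reduce = NULL) {
  stopifnot(inherits(grid, "parameter_grid"))
  n <- nrow(grid$points)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- tryCatch({
      pp <- grid_point_params(grid, i, wake_lux_threshold)
      init <- if (equilibration_days > 0) {
        equilibrate(pp$cparams, pp$sparams, lights_on = lights_on,
                    n_days = equilibration_days, dt = dt)$state
      } else NULL
      res <- simulate(schedule, pp$cparams, pp$sparams, initial = init, dt = dt)
      if (is.null(reduce)) res else reduce(res, i)
    }, error = function(e) e)
  }
  out
}

# Total sleep (hours) of `episodes` inside the window [w0, w1].
sleep_in_window <- function(episodes, w0, w1) {
  if (nrow(episodes) == 0) return(0)
  sum(pmax(pmin(episodes$offset, w1) - pmax(episodes$onset, w0), 0))
}

#' Physiological validity filter
#'
#' A parameter set is retained when, on every evaluated 24 h day (aligned to
#' the lights-on hour), it sleeps at least `min_sleep_h` hours in total and
#' switches between sleep and wake exactly twice (one onset, one offset; a
#' light-forced wake counts as the offset switch). The filter is applied on
#' the steady state of the equilibration schedule, so only the trailing
#' `eval_days` full days are judged.
#'
#' @param results list of [simulate()] results (or `episodes` data.frames),
#'   e.g. from [run_sweep()]. Condition objects (failed points) fail the
#'   filter with reason `"error"`.
#' @param min_sleep_h minimum nightly sleep in hours (inclusive bound).
#' @param eval_days number of trailing days to judge.
#' @param lights_on clock hour anchoring the day windows.
#' @return list with `retained` (integer indices) and `report` (data.frame
#'   with one row per input: `set`, `pass`, `reason`).
#' @export
filter_valid <- function(results, min_sleep_h = 6.5, eval_days = 5,
                         lights_on = 6) {
  judge <- function(res) {
    if (inherits(res, "condition")) return("error")
    ep <- if (is.data.frame(res)) res else res$episodes
    t_end <- if (is.data.frame(res)) max(res$offset) else max(res$time)
    last_anchor <- lights_on + 24 * floor((t_end - lights_on) / 24)
    starts <- last_anchor - 24 * seq_len(eval_days)
    if (any(starts < 0)) return("result spans fewer days than eval_days")
    for (w0 in starts) {
      w1 <- w0 + 24
      n_on <- sum(ep$onset >= w0 & ep$onset < w1)
      n_off <- sum(ep$offset >= w0 & ep$offset < w1)
      if (n_on + n_off != 2L || n_on != 1L) {
        return(sprintf("%d switches in day starting %.0f h", n_on + n_off, w0))
      }
      if (sleep_in_window(ep, w0, w1) < min_sleep_h) {
        return(sprintf("%.2f h sleep in day starting %.0f h",
                       sleep_in_window(ep, w0, w1), w0))
      }
    }
    "ok"
  }
  reasons <- vapply(results, judge, character(1))
  report <- data.frame(set = seq_along(results), pass = reasons == "ok",
                       reason = reasons)
  list(retained = which(report$pass), report = report)
}

#' Sleep-grid hyperparameter search
#'
#' Runs the full sleep-parameter grid on the regular 1000-lux 16:8 schedule
#' and applies the validity filter on its steady state, reproducing the
#' hyperparameter search that defines the retained sleep-phenotype ensemble.
#'
#' @param grid sleep grid (default [make_sleep_grid()]).
#' @param n_days days of the regular schedule per point.
#' @param dt integration step (hours).
#' @inheritParams filter_valid
#' @return list with `retained`, `report` (as [filter_valid()]) and `points`
#'   (the grid points with a `pass` column).
#' @export
sweep_sleep_filter <- function(grid = make_sleep_grid(), n_days = 30,
                               dt = 0.01, min_sleep_h = 6.5, eval_days = 5,
                               lights_on = 6) {
  sched <- build_equilibration_schedule(lights_on, n_days, 1000)
  eps <- run_sweep(grid, sched, equilibration_days = 0, dt = dt,
                   reduce = function(res, i) res$episodes)
  flt <- filter_valid(eps, min_sleep_h = min_sleep_h, eval_days = eval_days,
                      lights_on = lights_on)
  pts <- grid$points
  pts$pass <- flt$report$pass
  c(flt, list(points = pts))
}
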