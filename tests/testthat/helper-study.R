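# Shared, lazily computed study objects. The ensemble sweeps are deterministic
# and moderately expensive, so tests that need them share one computation.

.study_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .study_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .study_cache)
  }
  get(key, envir = .study_cache, inherits = FALSE)
}

get_sleep_filter <- function() cached("sleep_filter", sweep_sleep_filter())

get_chang_metrics <- function(kind, baseline) {
  cached(sprintf("chang_%s_%d", kind, baseline), {
    pts <- if (kind == "sleep") {
      f <- get_sleep_filter()
      f$points[f$points$pass, ]
    } else {
      make_circadian_grid()$points
    }
    run_chang_ensemble(pts, baseline_lux = baseline)
  })
}

get_pulse_run <- function(baseline, offset) {
  cached(sprintf("pulse_%d_%d", baseline, offset),
         run_pulse_simulation(baseline, offset))
}

dark_schedule <- function(n_days = 30) {
  light_schedule(data.frame(t_start = 0, t_end = 24 * n_days,
                            lux_start = 0, lux_end = 0), label = "dark")
}

# Sleep parameterization that never sleeps (for smooth-dynamics oracles).
awake_params <- function() {
  sleep_params(mu = 1e5, delta = 1, h_wake_asymptote = 2e5, chi_wake = 1e6,
               wake_lux_threshold = Inf)
}

# Minimal hand-built result object for analysis-function unit tests.
fake_result <- function(episodes, cbt_min = numeric(0), t_end = 24 * 15) {
  structure(list(time = c(0, t_end), episodes = episodes, cbt_min = cbt_min),
            class = "simulation_result")
}
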