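#' Photoreceptor activation rate
#'
#' The compressive light response \eqn{\alpha(I) = \alpha_0 (I/I_0)^p}: zero in
#' darkness, strictly increasing in illuminance, with curvature set by the
#' photic sensitivity exponent `p`. Returned in the activation-scale units of
#' the model (1/min); Process L converts to hourly rates internally.
#'
#' @param lux illuminance (>= 0), vectorized.
#' @param cparams a [circadian_params()].
#' @return activation rate, same length as `lux`.
#' @export
photic_activation <- function(lux, cparams = circadian_params()) {
  if (any(lux < 0)) stop("illuminance must be non-negative")
  cparams$alpha_0 * (lux / cparams$i_0)^cparams$p
}

#' Process L dynamics
#'
#' Photoreceptor saturation fraction `n` is driven up by light through
#' [photic_activation()] and recovers in darkness:
#' \deqn{dn/dt = 60\,[\alpha(I)(1 - n) - \beta n]} (per hour). In constant
#' light the fixed point is \eqn{n^* = \alpha/(\alpha+\beta) \in (0, 1]}.
#'
#' @param n saturation fraction in `[0, 1]`.
#' @param lux illuminance (>= 0).
#' @param cparams a [circadian_params()].
#' @return dn/dt in 1/h.
#' @export
process_l_derivative <- function(n, lux, cparams = circadian_params()) {
  a <- photic_activation(lux, cparams)
  60 * (a * (1 - n) - cparams$beta * n)
}

#' Photic drive onto the oscillator
#'
#' \deqn{B = G\,\alpha(I)\,(1-n)\,(1-\kappa x)(1-\kappa x_c).}
#' The `(1-n)` factor encodes retinal saturation (a fully saturated retina
#' transmits no drive) and the \eqn{(1-\kappa x)(1-\kappa x_c)} factor makes
#' identical light produce phase-dependent effects, shaping the phase response
#' curve.
#'
#' @param x,xc oscillator state variables.
#' @param n photoreceptor saturation fraction.
#' @param lux illuminance (>= 0).
#' @param cparams a [circadian_params()].
#' @return dimensionless drive B.
#' @export
light_drive <- function(x, xc, n, lux, cparams = circadian_params()) {
  a <- photic_activation(lux, cparams)
  cparams$g * a * (1 - n) * (1 - cparams$kappa * x) * (1 - cparams$kappa * xc)
}

#' Van der Pol oscillator right-hand side
#'
#' The circadian pacemaker is a van der Pol limit-cycle oscillator with an
#' intrinsic period `tau_c`, forced by the photic drive `B`:
#' \deqn{dx/dt = \frac{\pi}{12}\,(x_c + B)}
#' \deqn{dx_c/dt = \frac{\pi}{12}\left[\mu_v\left(x_c - \tfrac{4}{3}x_c^3\right)
#'   - x\left(\left(\frac{24}{f\,\tau_c}\right)^2 + k_B B\right)\right]}
#' with stiffness \eqn{\mu_v}, coupling \eqn{k_B} and calibration factor `f`
#' chosen so the dark limit-cycle period equals `tau_c`.
#'
#' @param x,xc oscillator state variables.
#' @param b photic drive from [light_drive()].
#' @param cparams a [circadian_params()].
#' @return numeric vector `c(dx, dxc)` in 1/h.
#' @export
oscillator_derivatives <- function(x, xc, b, cparams = circadian_params()) {
  omega2 <- (24 / (cparams$period_correction * cparams$tau_c))^2
  dx <- (pi / 12) * (xc + b)
  dxc <- (pi / 12) * (cparams$mu_vdp * (xc - (4 / 3) * xc^3) -
                        x * (omega2 + cparams$k_b * b))
  c(dx, dxc)
}

#' Homeostatic sleep pressure dynamics
#'
#' During wake, pressure rises with a saturating exponential towards
#' `h_wake_asymptote` with time constant `chi_wake`; during sleep it decays
#' exponentially with the swept time constant `chi`.
#'
#' @param h homeostatic pressure (>= 0).
#' @param asleep logical flag.
#' @param sparams a [sleep_params()].
#' @return dH/dt in units/h.
#' @export
homeostat_derivative <- function(h, asleep, sparams = sleep_params()) {
  ifelse(asleep, -h / sparams$chi,
         (sparams$h_wake_asymptote - h) / sparams$chi_wake)
}

#' Circadian-modulated sleep thresholds
#'
#' Upper (sleep-onset) and lower (wake) thresholds oscillate in parallel with
#' the circadian variable `x`, keeping a constant gap `delta`:
#' \eqn{H^+ = \mu + c_a x}, \eqn{H^- = \mu - \Delta + c_a x}.
#'
#' @param x oscillator variable (vectorized).
#' @param sparams a [sleep_params()].
#' @return list with numeric elements `upper` and `lower`.
#' @export
sleep_thresholds <- function(x, sparams = sleep_params()) {
  up <- sparams$mu + sparams$c_a * x
  list(upper = up, lower = up - sparams$delta)
}

#' Sleep/wake transition rule
#'
#' Wake-to-sleep requires homeostatic pressure at or above the upper threshold
#' *and* environmental light at or below `wake_lux_threshold` (sleep is
#' prevented in light, mimicking prescribed laboratory wake times).
#' Sleep-to-wake occurs when pressure falls to the lower threshold or when
#' light exceeds the threshold (forced wake). Otherwise the state is
#' unchanged.
#'
#' @param asleep current flag.
#' @param h homeostatic pressure.
#' @param upper,lower current thresholds (from [sleep_thresholds()]).
#' @param lux current environmental illuminance.
#' @param sparams a [sleep_params()].
#' @return logical: the next sleep flag.
#' @export
transition_rule <- function(asleep, h, upper, lower, lux,
                            sparams = sleep_params()) {
  if (asleep) {
    if (h <= lower || lux > sparams$wake_lux_threshold) FALSE else TRUE
  } else {
    if (h >= upper && lux <= sparams$wake_lux_threshold) TRUE else FALSE
  }
}

#' Core body temperature minimum times
#'
#' Locates one minimum of the oscillator variable `x` per circadian cycle:
#' grid local minima refined by three-point quadratic interpolation, with
#' candidates closer than `min_separation` collapsed to the deeper one
#' (earliest time on exact ties).
#'
#' @param t time grid in hours (strictly increasing, uniform).
#' @param x oscillator variable sampled on `t`.
#' @param min_separation minimum spacing between reported minima (hours).
#' @return numeric vector of refined minimum times (possibly empty).
#' @export
cbt_min_times <- function(t, x, min_separation = 12) {
  stopifnot(length(t) == length(x))
  if (length(t) < 3 || (t[length(t)] - t[1]) < 24) return(numeric(0))
  i <- which(diff(sign(diff(x))) > 0) + 1L  # strict local minima on the grid
  if (length(i) == 0) return(numeric(0))
  # quadratic refinement around each grid minimum
  refine <- function(j) {
    x0 <- x[j - 1]; x1 <- x[j]; x2 <- x[j + 1]
    denom <- x0 - 2 * x1 + x2
    if (denom <= 0) return(t[j])
    dt <- t[j + 1] - t[j]
    t[j] + 0.5 * dt * (x0 - x2) / denom
  }
  times <- vapply(i, refine, numeric(1))
  depth <- x[i]
  keep_t <- numeric(0)
  keep_d <- numeric(0)
  for (k in seq_along(times)) {
    if (length(keep_t) > 0 && times[k] - keep_t[length(keep_t)] < min_separation) {
      if (depth[k] < keep_d[length(keep_d)]) {
        keep_t[length(keep_t)] <- times[k]
        keep_d[length(keep_d)] <- depth[k]
      }
    } else {
      keep_t <- c(keep_t, times[k])
      keep_d <- c(keep_d, depth[k])
    }
  }
  keep_t
}

#' Dim light melatonin onset times
#'
#' DLMO is taken to precede the core body temperature minimum by a fixed 7 h.
#'
#' @param cbt_min numeric vector of CBTmin times (hours).
#' @return numeric vector of DLMO times.
#' @export
dlmo_times <- function(cbt_min) {
  cbt_min - 7
}

#' Average circadian amplitude over a window
#'
#' Time-average (trapezoid rule) of the instantaneous amplitude
#' \eqn{r(t) = \sqrt{x^2 + x_c^2}} over a window, by default the final
#' simulated day.
#'
#' @param t time grid (hours).
#' @param x,xc oscillator variables sampled on `t`.
#' @param window `c(from, to)` in hours; default the last 24 h of `t`.
#' @return dimensionless average amplitude.
#' @export
average_amplitude <- function(t, x, xc, window = NULL) {
  if (is.null(window)) window <- c(t[length(t)] - 24, t[length(t)])
  if (window[1] < t[1] - 1e-9 || window[2] > t[length(t)] + 1e-9) {
    stop("window outside trajectory range")
  }
  sel <- t >= window[1] - 1e-9 & t <= window[2] + 1e-9
  tt <- t[sel]
  r <- sqrt(x[sel]^2 + xc[sel]^2)
  if (length(tt) < 2) stop("window contains fewer than two samples")
  sum(diff(tt) * (r[-1] + r[-length(r)]) / 2) / (tt[length(tt)] - tt[1])
}
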