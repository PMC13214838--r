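#' Circadian pacemaker parameters
#'
#' Parameters of the light-driven van der Pol limit-cycle oscillator and its
#' photoreceptor saturation process (Process L). Three parameters define the
#' swept circadian phenotype:
#' \describe{
#'   \item{p}{photic sensitivity exponent of the activation function
#'     \eqn{\alpha(I) = \alpha_0 (I/I_0)^p} (dimensionless, sweep range
#'     0.5-0.7, default 0.5).}
#'   \item{kappa}{shape constant of the state modulation
#'     \eqn{(1-\kappa x)(1-\kappa x_c)} of the photic drive, which sets the
#'     shape of the phase response curve (dimensionless, sweep range 0.4-0.7,
#'     default 0.4).}
#'   \item{tau_c}{intrinsic circadian period in hours (sweep range 23.8-24.4,
#'     default 24.2).}
#' }
#' The remaining constants are the literature values of the reference
#' oscillator: activation scale `alpha_0` (1/min), photoreceptor recovery rate
#' `beta` (1/min), half-saturation illuminance `i_0` (lux), drive gain `g`,
#' drive-to-frequency coupling `k_b`, van der Pol stiffness `mu_vdp`, and the
#' `period_correction` factor that makes the dark limit-cycle period equal
#' `tau_c`.
#'
#' @param p,kappa,tau_c swept phenotype parameters (see Details).
#' @param alpha_0,beta,i_0,g,k_b,mu_vdp,period_correction fixed constants;
#'   override only for sensitivity analyses.
#' @return An object of class `circadian_params` (named list).
#' @export
circadian_params <- function(p = 0.5, kappa = 0.4, tau_c = 24.2,
                             alpha_0 = 0.05, beta = 0.0075, i_0 = 9500,
                             g = 33.75, k_b = 0.55, mu_vdp = 0.23,
                             period_correction = 0.99669) {
  stopifnot(tau_c > 0, alpha_0 > 0, beta > 0, i_0 > 0, g > 0,
            k_b > 0, mu_vdp > 0, period_correction > 0, p > 0, kappa >= 0)
  structure(list(p = p, kappa = kappa, tau_c = tau_c,
                 alpha_0 = alpha_0, beta = beta, i_0 = i_0, g = g,
                 k_b = k_b, mu_vdp = mu_vdp,
                 period_correction = period_correction),
            class = "circadian_params")
}

#' Two-process sleep homeostat parameters
#'
#' Homeostatic sleep pressure `H` rises during wake, saturating towards the
#' asymptote `h_wake_asymptote` with time constant `chi_wake`, and decays
#' exponentially during sleep with time constant `chi`. Sleep onset and offset
#' occur when `H` crosses the circadian-modulated upper and lower thresholds
#' \deqn{H^+(t) = \mu + c_a x(t), \qquad H^-(t) = \mu - \Delta + c_a x(t),}
#' where `x` is the oscillator variable. Three parameters define the swept
#' sleep phenotype:
#' \describe{
#'   \item{mu}{mean upper-threshold level (homeostat units, sweep range
#'     17.5-19.5, default 19.0).}
#'   \item{delta}{upper-minus-lower threshold gap (sweep range 5-9,
#'     default 6.0).}
#'   \item{chi}{sleep-phase decay time constant in hours (sweep range 7-11,
#'     default 11.0).}
#' }
#' `wake_lux_threshold` (default 0.5 lux) implements the laboratory rule that
#' sleep is prevented, and ongoing sleep terminated, whenever environmental
#' light exceeds it; set it to `Inf` for schedules where sleep timing is fully
#' endogenous (the baseline-plus-pulse simulations, whose 50 lux nighttime
#' floor would otherwise forbid sleep entirely).
#'
#' @param mu,delta,chi swept phenotype parameters (see Details).
#' @param c_a circadian modulation amplitude of both thresholds.
#' @param h_wake_asymptote,chi_wake wake-phase rise law constants.
#' @param wake_lux_threshold lux above which sleep is prevented/terminated.
#' @return An object of class `sleep_params` (named list).
#' @export
sleep_params <- function(mu = 19.0, delta = 6.0, chi = 11.0,
                         c_a = 4.0, h_wake_asymptote = 23.5, chi_wake = 18.2,
                         wake_lux_threshold = 0.5) {
  stopifnot(delta > 0, chi > 0, mu > delta, chi_wake > 0,
            h_wake_asymptote > mu, wake_lux_threshold >= 0)
  structure(list(mu = mu, delta = delta, chi = chi, c_a = c_a,
                 h_wake_asymptote = h_wake_asymptote, chi_wake = chi_wake,
                 wake_lux_threshold = wake_lux_threshold),
            class = "sleep_params")
}

#' Model constants table
#'
#' One row per constant of the coupled model, with its value, units and role.
#' Swept phenotype parameters are reported at the supplied values.
#'
#' @param cparams a [circadian_params()].
#' @param sparams a [sleep_params()].
#' @return data.frame with columns `name`, `value`, `units`, `role`.
#' @export
constants_table <- function(cparams = circadian_params(),
                            sparams = sleep_params()) {
  data.frame(
    name = c("p", "kappa", "tau_c", "alpha_0", "beta", "i_0", "g", "k_b",
             "mu_vdp", "period_correction",
             "mu", "delta", "chi", "c_a", "h_wake_asymptote", "chi_wake",
             "wake_lux_threshold"),
    value = c(cparams$p, cparams$kappa, cparams$tau_c, cparams$alpha_0,
              cparams$beta, cparams$i_0, cparams$g, cparams$k_b,
              cparams$mu_vdp, cparams$period_correction,
              sparams$mu, sparams$delta, sparams$chi, sparams$c_a,
              sparams$h_wake_asymptote, sparams$chi_wake,
              sparams$wake_lux_threshold),
    units = c("-", "-", "h", "1/min", "1/min", "lux", "-", "-", "-", "-",
              "homeostat units", "homeostat units", "h", "homeostat units",
              "homeostat units", "h", "lux"),
    role = c("photic sensitivity exponent (swept)",
             "drive state-modulation / PRC shape (swept)",
             "intrinsic circadian period (swept)",
             "Process L activation scale",
             "Process L recovery rate",
             "half-saturation illuminance",
             "photic drive gain",
             "drive-to-frequency coupling",
             "van der Pol stiffness",
             "dark-period calibration factor",
             "mean upper sleep-pressure threshold (swept)",
             "upper-minus-lower threshold gap (swept)",
             "sleep-phase pressure decay time constant (swept)",
             "circadian threshold modulation amplitude",
             "wake-phase pressure asymptote",
             "wake-phase pressure rise time constant",
             "light level preventing/terminating sleep")
  )
}

#' @rdname constants_table
#' @param path file path for the JSON export.
#' @export
write_constants_json <- function(path, cparams = circadian_params(),
                                 sparams = sleep_params()) {
  jsonlite::write_json(constants_table(cparams, sparams), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

as_cpar_vec <- function(cp) {
  stopifnot(inherits(cp, "circadian_params"))
  unlist(cp[c("p", "kappa", "tau_c", "alpha_0", "beta", "i_0", "g",
              "k_b", "mu_vdp", "period_correction")])
}

as_spar_vec <- function(sp) {
  stopifnot(inherits(sp, "sleep_params"))
  unlist(sp[c("mu", "delta", "chi", "c_a", "h_wake_asymptote", "chi_wake",
              "wake_lux_threshold")])
}
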