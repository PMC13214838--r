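#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Coupled circadian (van der Pol + Process L) and two-process sleep model,
// integrated with a fixed-step classical RK4 scheme. Sleep/wake transitions
// and light-forcing events are localized by bisection inside the step so that
// onset/offset times carry sub-step (1e-5 h) precision. The integration is
// fully deterministic: identical inputs give bit-identical trajectories.

struct Schedule {
  const double *t0, *t1, *l0, *l1;
  int n;
  double lux(double t) const {
    // right-continuous piecewise-linear evaluation; binary search
    int lo = 0, hi = n - 1;
    if (t <= t0[0]) return l0[0];
    if (t >= t1[n - 1]) return l1[n - 1];
    while (lo < hi) {
      int mid = (lo + hi + 1) / 2;
      if (t0[mid] <= t) lo = mid; else hi = mid - 1;
    }
    double f = (t - t0[lo]) / (t1[lo] - t0[lo]);
    double v = l0[lo] + f * (l1[lo] - l0[lo]);
    return v > 0 ? v : 0;
  }
};

struct CPar {
  double p, kappa, tau_c, alpha_0, beta, i_0, g, k_b, mu_vdp, corr, omega2;
};
struct SPar {
  double mu, delta, chi, c_a, h_asym, chi_wake, wake_lux;
};

struct State { double x, xc, n, h; };

static inline void deriv(const State &s, double lux_env, bool asleep,
                         const CPar &c, const SPar &sp, State &d) {
  double I = asleep ? 0.0 : lux_env;
  double alpha = I > 0 ? c.alpha_0 * std::pow(I / c.i_0, c.p) : 0.0;
  double B = c.g * alpha * (1.0 - s.n) *
             (1.0 - c.kappa * s.x) * (1.0 - c.kappa * s.xc);
  d.x = (M_PI / 12.0) * (s.xc + B);
  d.xc = (M_PI / 12.0) * (c.mu_vdp * (s.xc - (4.0 / 3.0) * s.xc * s.xc * s.xc)
                          - s.x * (c.omega2 + c.k_b * B));
  d.n = 60.0 * (alpha * (1.0 - s.n) - c.beta * s.n);
  d.h = asleep ? -s.h / sp.chi : (sp.h_asym - s.h) / sp.chi_wake;
}

static inline void rk4(const State &s0, double t, double h, bool asleep,
                       const Schedule &sch, const CPar &c, const SPar &sp,
                       State &out) {
  State k1, k2, k3, k4, tmp;
  double luxa = sch.lux(t), luxb = sch.lux(t + 0.5 * h), luxc = sch.lux(t + h);
  deriv(s0, luxa, asleep, c, sp, k1);
  tmp = {s0.x + 0.5 * h * k1.x, s0.xc + 0.5 * h * k1.xc,
         s0.n + 0.5 * h * k1.n, s0.h + 0.5 * h * k1.h};
  deriv(tmp, luxb, asleep, c, sp, k2);
  tmp = {s0.x + 0.5 * h * k2.x, s0.xc + 0.5 * h * k2.xc,
         s0.n + 0.5 * h * k2.n, s0.h + 0.5 * h * k2.h};
  deriv(tmp, luxb, asleep, c, sp, k3);
  tmp = {s0.x + h * k3.x, s0.xc + h * k3.xc,
         s0.n + h * k3.n, s0.h + h * k3.h};
  deriv(tmp, luxc, asleep, c, sp, k4);
  out.x = s0.x + h / 6.0 * (k1.x + 2 * k2.x + 2 * k3.x + k4.x);
  out.xc = s0.xc + h / 6.0 * (k1.xc + 2 * k2.xc + 2 * k3.xc + k4.xc);
  out.n = s0.n + h / 6.0 * (k1.n + 2 * k2.n + 2 * k3.n + k4.n);
  out.h = s0.h + h / 6.0 * (k1.h + 2 * k2.h + 2 * k3.h + k4.h);
  if (out.n < 0) out.n = 0;
  if (out.n > 1) out.n = 1;
}

// Transition condition evaluated at (state, t): would the sleep flag flip?
static inline bool transition_due(const State &s, double t, bool asleep,
                                  const Schedule &sch, const SPar &sp,
                                  bool &forced) {
  double lux = sch.lux(t);
  double upper = sp.mu + sp.c_a * s.x;
  double lower = upper - sp.delta;
  forced = false;
  if (asleep) {
    if (lux > sp.wake_lux) { forced = (s.h > lower); return true; }
    return s.h <= lower;
  }
  return (s.h >= upper) && (lux <= sp.wake_lux);
}

// [[Rcpp::export]]
List simulate_core(NumericMatrix segments, double t_begin, double t_finish,
                   double dt, NumericVector cpar, NumericVector spar,
                   NumericVector init) {
  if (dt <= 0 || dt > 0.1) stop("dt must be in (0, 0.1] hours");
  CPar c = {cpar[0], cpar[1], cpar[2], cpar[3], cpar[4], cpar[5], cpar[6],
            cpar[7], cpar[8], cpar[9], 0.0};
  double q = 24.0 / (c.corr * c.tau_c);
  c.omega2 = q * q;
  SPar sp = {spar[0], spar[1], spar[2], spar[3], spar[4], spar[5], spar[6]};
  Schedule sch;
  NumericVector s_t0 = segments(_, 0), s_t1 = segments(_, 1),
                s_l0 = segments(_, 2), s_l1 = segments(_, 3);
  sch.t0 = s_t0.begin(); sch.t1 = s_t1.begin();
  sch.l0 = s_l0.begin(); sch.l1 = s_l1.begin();
  sch.n = segments.nrow();

  int nsteps = (int)std::llround((t_finish - t_begin) / dt);
  if (nsteps < 1 || std::fabs(t_begin + nsteps * dt - t_finish) > 1e-8) {
    stop("(t_finish - t_begin) must be a positive multiple of dt");
  }

  NumericVector out_t(nsteps + 1), out_x(nsteps + 1), out_xc(nsteps + 1),
                out_n(nsteps + 1), out_h(nsteps + 1);
  IntegerVector out_sleep(nsteps + 1);

  State s = {init[0], init[1], init[2], init[3]};
  bool asleep = init[4] > 0.5;

  std::vector<double> ep_on, ep_off;
  std::vector<int> ep_forced;
  if (asleep) { ep_on.push_back(t_begin); ep_forced.push_back(NA_INTEGER); }

  out_t[0] = t_begin; out_x[0] = s.x; out_xc[0] = s.xc; out_n[0] = s.n;
  out_h[0] = s.h; out_sleep[0] = asleep ? 1 : 0;

  for (int k = 0; k < nsteps; ++k) {
    double t = t_begin + (double)k * dt;
    double t_next = t_begin + (double)(k + 1) * dt;
    double t_cur = t;
    int guard = 0;
    while (t_cur < t_next - 1e-12) {
      double hstep = t_next - t_cur;
      State s1;
      rk4(s, t_cur, hstep, asleep, sch, c, sp, s1);
      bool forced;
      if (transition_due(s1, t_cur + hstep, asleep, sch, sp, forced)) {
        // bisection for the event time in (t_cur, t_cur + hstep]
        double a = t_cur, b = t_cur + hstep;
        State sb = s1;
        while (b - a > 1e-5) {
          double m = 0.5 * (a + b);
          State sm;
          rk4(s, t_cur, m - t_cur, asleep, sch, c, sp, sm);
          bool f2;
          if (transition_due(sm, m, asleep, sch, sp, f2)) {
            b = m; sb = sm;
          } else {
            a = m;
          }
        }
        transition_due(sb, b, asleep, sch, sp, forced);
        if (asleep) {
          ep_off.push_back(b);
          if (ep_forced.back() == NA_INTEGER) ep_forced.back() = forced ? 1 : 0;
          else ep_forced.back() = forced ? 1 : 0;
          asleep = false;
        } else {
          ep_on.push_back(b);
          ep_forced.push_back(NA_INTEGER);
          asleep = true;
        }
        s = sb;
        t_cur = b;
        if (++guard > 10) stop("too many sleep/wake events within one step at t = %f", t_cur);
      } else {
        s = s1;
        t_cur = t_next;
      }
    }
    if (!std::isfinite(s.x) || !std::isfinite(s.xc) ||
        !std::isfinite(s.n) || !std::isfinite(s.h)) {
      stop("non-finite state at t = %f (p=%f kappa=%f tau_c=%f mu=%f delta=%f chi=%f)",
           t_next, c.p, c.kappa, c.tau_c, sp.mu, sp.delta, sp.chi);
    }
    out_t[k + 1] = t_next; out_x[k + 1] = s.x; out_xc[k + 1] = s.xc;
    out_n[k + 1] = s.n; out_h[k + 1] = s.h; out_sleep[k + 1] = asleep ? 1 : 0;
  }

  if (asleep) ep_off.push_back(t_finish);  // truncated final episode
  int ne = ep_on.size();
  NumericVector eon(ne), eoff(ne);
  IntegerVector efo(ne);
  for (int i = 0; i < ne; ++i) {
    eon[i] = ep_on[i];
    eoff[i] = ep_off[i];
    efo[i] = ep_forced[i];
  }
  NumericVector fin = NumericVector::create(s.x, s.xc, s.n, s.h,
                                            asleep ? 1.0 : 0.0);
  return List::create(_["t"] = out_t, _["x"] = out_x, _["xc"] = out_xc,
                      _["n"] = out_n, _["H"] = out_h, _["asleep"] = out_sleep,
                      _["ep_onset"] = eon, _["ep_offset"] = eoff,
                      _["ep_forced"] = efo, _["final"] = fin);
}
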