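---
title: "Modeling full-day light exposure, sleep timing and circadian phase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling full-day light exposure, sleep timing and circadian phase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`circalux` simulates how the pattern of light across the whole 24 h day — not
just morning or evening light in isolation — shapes sleep timing and circadian
phase. It couples a light-driven limit-cycle model of the human circadian
pacemaker to a two-process sleep homeostat, drives the coupled system with
constructed laboratory light schedules, and sweeps phenotype parameter grids
to produce ensemble-level outcomes: sleep onset latencies, phase-marker
shifts, entrainment classification and circadian amplitude.

## The model

### Circadian pacemaker (Process L + van der Pol oscillator)

Light acts through a photoreceptor activation-and-saturation stage
(Process L). Illuminance $I$ (lux) produces an activation rate with a
compressive power law, and the usable photoreceptor fraction $1 - n$ is
depleted by light and recovers in darkness:

$$\alpha(I) = \alpha_0 \left(\frac{I}{I_0}\right)^p, \qquad
\dot n = 60\,[\alpha(I)(1 - n) - \beta n].$$

The photic drive onto the pacemaker is gated by the available retina and
modulated by the oscillator state, which is what gives light a phase-dependent
effect (the phase response curve):

$$B = G\,\alpha(I)\,(1 - n)\,(1 - \kappa x)(1 - \kappa x_c).$$

The pacemaker itself is a van der Pol-type limit-cycle oscillator with
intrinsic period $\tau_C$:

$$\dot x = \frac{\pi}{12}(x_c + B), \qquad
\dot x_c = \frac{\pi}{12}\Big[\mu_v\big(x_c - \tfrac{4}{3}x_c^3\big)
 - x\Big(\big(\tfrac{24}{f\,\tau_C}\big)^2 + k_B B\Big)\Big].$$

This is the classical Forger–Jewett–Kronauer (1999) formulation with its
published constants ($\alpha_0 = 0.05\,\mathrm{min}^{-1}$,
$\beta = 0.0075\,\mathrm{min}^{-1}$, $I_0 = 9500$ lux, $G = 33.75$,
$k_B = 0.55$, $\mu_v = 0.23$, $f = 0.99669$), the composition with a sleep
homeostat following Skeldon and colleagues. The minimum of $x$ is read as the
core body temperature minimum (CBTmin); dim light melatonin onset (DLMO) is
taken as CBTmin $-$ 7 h. During sleep the eyes are closed and the circadian
light input is zero.

Three parameters define the swept *circadian phenotype*: the photic
sensitivity exponent $p \in [0.5, 0.7]$ (default 0.5), the drive-modulation
shape $\kappa \in [0.4, 0.7]$ (default 0.4; this constant shapes the phase
response curve), and the intrinsic period $\tau_C \in [23.8, 24.4]$ h
(default 24.2). In darkness the simulated free-running period equals
$\tau_C$ within 0.05 h (a standing test), and `phase_response_curve()`
confirms the textbook sign structure: light after CBTmin advances, light
before it delays, with isolated dead points rather than an extended dead
zone.

### Two-process sleep homeostat

Homeostatic pressure $H$ rises during wake, saturating towards an asymptote,
and decays exponentially during sleep:

$$\dot H = \begin{cases}
 (H_a - H)/\chi_w & \text{awake} \\
 -H/\chi & \text{asleep.}
\end{cases}$$

Sleep onset occurs when $H$ reaches the circadian-modulated upper threshold
and wake when it falls to the lower one:

$$H^+(t) = \mu + c_a\,x(t), \qquad H^-(t) = \mu - \Delta + c_a\,x(t).$$

The swept *sleep phenotype* is $\mu \in [17.5, 19.5]$ (mean upper-threshold
level, default 19), $\Delta \in [5, 9]$ (threshold gap, default 6) and
$\chi \in [7, 11]$ h (sleep-phase decay constant, default 11). A laboratory
rule overrides the thresholds: in protocol simulations, environmental light
above 0.5 lux prevents sleep onset and terminates ongoing sleep, which is how
scheduled wake times are imposed on the model.

**Calibration of the fixed homeostat constants.** The wake-rise law and the
threshold modulation amplitude are not part of the swept phenotype and are
not uniquely fixed by the published two-process literature, where several
variants coexist. We set $\chi_w = 18.2$ h (the classical two-process rise
constant) and chose $H_a = 23.5$ and $c_a = 4.0$ once, so that the *default*
phenotype on the regular bright schedule (1000 lux, 06:00–22:00) shows
textbook sleep physiology: spontaneous onset 10–20 min after the 22:00
lights-off and roughly 7–7.5 h of consolidated sleep ending near lights-on.
These two numbers are the package's main free calibration; every headline
quantity that depends on the *ensemble's* evening threshold geometry (the
latency-difference means, the validity-filter count) inherits uncertainty
from them, and deviations of recomputed values from published reference
values concentrate exactly there. The full constants table is exported by
`constants_table()` / `write_constants_json()`.

### Integration and events

The coupled system is integrated with a fixed-step classical Runge–Kutta
scheme at `dt = 0.01` h (about 100 steps per hour, implemented in C++).
Sleep/wake transitions and light-forcing events are localized inside a step
by bisection to $10^{-5}$ h, so onset latencies carry sub-minute precision;
CBTmin is located by grid minima refined with three-point quadratic
interpolation (ties broken to the earliest time, minima closer than 12 h
collapsed to the deeper one). Schedules are piecewise linear and
right-continuous at step changes, and their breakpoints fall on the
integration grid, so discontinuities never straddle a step. The run is
deterministic — identical inputs give bit-identical trajectories, and there
is no random number use anywhere in the pipeline. Standing numerical checks:
step halving moves the final equilibrated CBTmin by well under 0.005 h, the
no-event dynamics agree with an adaptive reference solver (`deSolve`, in the
test suite) to $10^{-8}$, and $n$ never leaves $[0, 1]$.

## The light schedules (the synthetic-data generator)

All inputs are generated by the `protocols` functions; there is no external
data.

* `build_chang_schedule()` — a two-week evening-reading laboratory protocol:
  daytime baseline (90 lux, or 500 lux for the bright-day variant) from 06:00,
  a reading window 18:00–22:00 at 30 lux (eBook) or 3 lux (paper book), dark
  sleep opportunity 22:00–06:00, five reading days per condition and two
  constant-posture (CP) assessment days closing each week. The CP lux is not
  published for the original protocol; we use 3 lux (dim-light melatonin
  assessment convention) and keep it configurable. Week 1 occupies days 1–7
  and week 2 days 8–14; phase read-outs are the CBTmin markers falling in
  days 7 and 13, matching the published trajectory figures' comparison days.
  This convention is asymmetric (the week-1 marker sits one dim washout night
  after the last reading night, the week-2 marker immediately after it); the
  alternative readings (days 6/13 or 7/14) move the order-dependent phase
  attributions by roughly 10–20 min.
* `build_equilibration_schedule()` — a regular 16:8 day at 1000 lux with a
  configurable lights-on hour (05:00–09:00 emulates different habitual
  pre-study routines). Every protocol run starts from 30 days of this
  schedule; equilibration is idempotent to under a minute of CBTmin, so the
  documented initial state (dark limit cycle at its $x$-minimum, $n = 0$,
  $H$ at the lower threshold, awake) does not leak into results.
* `build_pulse_schedule()` — a ramped baseline day (nighttime floor 50 lux,
  or 0 in the full-darkness case; linear ramps 06:00–08:00 up and 20:00–22:00
  down) carrying a 1 h, 5000 lux rectangular pulse 0–14 h after the 06:00
  waking reference. Pulses are placed by clock time, not by the model's
  endogenous wake, so the forcing is identical across parameter sets. An
  alternative ramp dialect (`"caption"`, down-ramp 18:00–20:00) is exposed but
  unused in the mainline analyses. In pulse runs sleep timing is fully
  endogenous — the 0.5 lux rule is a reading-protocol device and would forbid
  sleep entirely under the 50 lux floor. Pulse runs last 20 days (plus half a
  day so the final night completes), start at the model's entrained phase on
  bright regular schedules (CBTmin near 03:00), and the last day is analysed.

What the generator deliberately does **not** emulate: spectral composition
and melanopic weighting, sporadic real-world light exposure, naps and social
constraints, and melatonin dynamics (DLMO here is a fixed offset from the
oscillator minimum, so melatonin suppression by light is out of scope).
Passing tests therefore demonstrate faithfulness to these idealized
laboratory forcing patterns, not to free-living light exposure.

## Ensembles, filtering and outcomes

`make_sleep_grid()` and `make_circadian_grid()` build 5 × 5 × 5 grids with
inclusive endpoints (125 sets each) — the unique three-axis factorization of
the published ensemble size. `sweep_sleep_filter()` runs the sleep grid for
30 days on the regular schedule and retains sets that, in steady state (the
last five days), sleep at least 6.5 h per lights-on-aligned day with exactly
one onset and one offset; "at least" rather than "more than" follows the
filter's own target phrasing. `run_chang_ensemble()` pushes a parameter table
through the full equilibrate-then-protocol pipeline for both condition orders
and returns per-night sleep onset latencies (scheduled 22:00 bedtime to model
onset; nights without sleep are missing, never zero) and the
eBook-attributable phase shift (positive = the eBook left the clock later
than the book). `summarize_ensemble()` reduces that to condition means, the
mean eBook-minus-Book latency difference and per-order phase-shift medians
and IQRs.

Problem sizes used throughout (chosen as the study's own design): 125-set
grids, 30-day equilibrations, 14-day protocol runs at `dt = 0.01` h, 20-day
pulse runs, and an 11 × 15 amplitude map. The complete pipeline —
`analysis/01` through `analysis/06`, or `scripts/acceptance.R` — runs in a
few minutes on one CPU.

## Design choices made where the design was open

* **Which constant the drive-shape parameter is.** Its name, default and
  range identify it with the oscillator-state modulation factor
  $(1-\kappa x)(1-\kappa x_c)$ of the classical drive; no other constant of
  that model has a 0.4 default inside a [0.4, 0.7] range.
* **Separate wake-rise timescale.** The swept $\chi$ governs only the
  sleep-phase decay; the wake rise keeps its own fixed classical constant.
  A single-timescale reading is possible but makes "sleep pressure decay
  rate" govern wake dynamics too, which the name argues against.
* **Forced-wake semantics.** Light above 0.5 lux both prevents onset and
  terminates ongoing sleep in protocol runs, because the emulated protocols
  prescribe wake times via lights-on.
* **Filter evaluation.** The validity filter judges the steady state of the
  regular schedule (hyperparameter-search stage), not the protocol runs.
* **Amplitude definition.** Instantaneous $\sqrt{x^2 + x_c^2}$ averaged over
  the last simulated day, kept in one function (`average_amplitude()`) so it
  can be swapped.
* **CP-day read-outs at days 7 and 13**, as discussed above.

## Known limitations

The fixed homeostat constants are a calibration, not a literature value; the
retained-ensemble latency statistics and the validity-filter count are
sensitive to them. With the chosen calibration, grid members with low upper
thresholds reach the sleep threshold before the 22:00 lights-off and show
zero latency, which compresses ensemble latency differences relative to a
regime where every onset is gated by the falling circadian threshold. The
asymmetric CP read-out convention shifts order-dependent phase attributions
by up to ~15 min. Entrainment classification at a 20-day horizon retains a
small transient for dim baselines (the 100-lux wake-pulse schedule still
drifts $-0.04$ h/day at day 20 and settles by day 60). Finally, this is a
deterministic phenotype-grid study: the ensembles express parameter
uncertainty, not within-individual noise.

```{r example}
library(circalux)
run <- run_chang_protocol(baseline_lux = 90, order = "ebook_first")
run$sol                 # per-night sleep onset latencies, both conditions
run$ebook_shift_min     # eBook-attributable phase shift (min, delay positive)
```
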