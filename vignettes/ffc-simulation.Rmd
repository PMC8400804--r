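---
title: "Modelling a fixed-point fuzzy feedback controller for FES-driven knee extension"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a fixed-point fuzzy feedback controller for FES-driven knee extension}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffcsim)
```

## The control problem

Functional electrical stimulation (FES) restores movement in paralysed
limbs by delivering short current pulses to a muscle.  In a closed-loop
knee-extension exercise the charge per stimulation cycle is encoded in the
stimulus **pulse width** (100–500 µs at 20–50 Hz), and a feedback
controller adjusts that width so the shank, hanging at 0°, extends to and
holds a target angle (70°, 40° or 30°).  Too much charge overshoots the
target and fatigues the muscle early; too little never reaches it.

`ffcsim` models the digital controller that closes this loop on an FPGA:
a zero-order Takagi–Sugeno fuzzy logic controller (FLC) implemented
entirely in 8/16-bit integer arithmetic, together with the acquisition
state machines around it and a knee-extension plant to exercise it
against.  Every stage exists twice: a bit-exact integer datapath (the
object of study) and a real-valued reference pipeline
(`flc_step_float()`) that plays the role of the continuous design model
the hardware is validated against.

## The controller

At each 100 ms sample the controller forms the error and change in error

$$E_k = \theta_{\mathrm{ref}} - \theta_{\mathrm{act},k}, \qquad
  dE_k = E_k - E_{k-1},$$

clamps both to the fuzzy domain $[-20°, 20°]$ and scales them onto the
8-bit range by

$$x_{255} = \left\lfloor \frac{(x + 20)\,255}{40} \right\rfloor,$$

so $-20 \mapsto 0$, $0 \mapsto 127$, $20 \mapsto 255$.  Five triangular
membership functions per input (NB, NS, ZE, PS, PB, breakpoints
0/63/127/191/255) fuzzify the scaled values; the 5×5 rule base combines
them with min-inference; and the crisp output is the singleton
centre-of-gravity

$$u = \left\lfloor \frac{\sum_{i=1}^{25} \min_i c_i}{\sum_{i=1}^{25} \min_i} \right\rfloor,$$

where the $c_i$ are the five singleton positions (VS…VB) of the table
selected by the reference angle.  The pulse width is $u \times 10$ µs.

```{r}
st <- flc_step(70, 4, prev_err = 70)
st$result$fired_rules
c(defuzzy = st$result$defuzzy, pulse = st$result$pulse)
```

Three integer-arithmetic details matter and are deliberate:

* **One floor at the end of each rational expression.**  Edge memberships
  are `floor(255 * (x - a) / (b - a))`, never a pre-divided slope
  `(255 / (b - a)) * (x - a)`.  Pre-division truncates the slope to an
  integer and cannot return 255 at the peak; only the end-floor form
  reproduces the documented membership values and the worked single-step
  output above.
* **Shoulder sets at the scale ends.**  NB is encoded (0, 0, 63) and PB
  (191, 255, 255): a clamped input at either end of the scale receives
  full membership 255.  Literal symmetric triangles would return 0 there
  and the controller would lose authority exactly where the error is
  largest.
* **The previous-error register stores the raw error.**  Clamping happens
  only inside the scaling step, so after a large transient the change in
  error is computed against the true previous error (e.g. $E = 66$
  followed by $dE = 66 - 70 = -4$), not against its clamped image.

With these choices the five memberships of any scaled input sum to 254 or
255 (a partition of unity up to one unit of floor loss per overlap pair),
the defuzzified output is always bounded by the singleton range, and the
integer output never deviates from the real-valued pipeline by more than
2 defuzzy units anywhere on the error grid — all verified exhaustively in
the test suite, including a brute-force re-evaluation of all 256×256
scaled input pairs against a literal loop over the printed rule grid.

At power-on both error registers are zero, so the datapath presents the
ME singleton (38 for the 70° table) before the first sample arrives; a
first sample at 0° saturates both inputs positive and fires the lone VB
rule (45); a sweep held at 90° saturates the error negative and ends at
the VS singleton (15).  These analytically forced points anchor the
integer pipeline in the tests.

The defuzzy/pulse registers are carried at 16 bits in trace formats; with
singletons in 10–50 the values never exceed 8 bits, so the width is
observationally irrelevant but fixed for output stability.

## The state machines

The cycle-level layer runs at a 1 µs tick (the 1 MHz clock a 50 MHz
master is divided down to; the divider itself is abstracted since nothing
reported resolves below 1 µs).  An acquisition is triggered every
100 ms — the first one 100 ms after reset, a convention this simulator
fixes since only the periodicity is prescribed — and proceeds
Idle → SOC (80 µs, `cs`/`wr` low) → Delay (until the converter's
interrupt falls) → EOC (80 µs, `cs`/`rd` low, data latched) → Idle, with
the `sample_data_ADC` strobe on EOC exit.  At the hardware conversion
latency of 75 µs the cycle takes $80 + 75 + 80 = 235$ µs; with the
interrupt tied low (the testbench condition) the Delay state is a
single-cycle transit, which this model takes as exactly 1 µs.  The
error-conversion FSM then needs exactly three ticks (Sample, Calculate,
Store) before the defuzzy and pulse registers update — everything
downstream of it is combinational — giving the 238 µs trigger-to-output
latency:

```{r}
run_acquisition_cycle(101)$duration_us
run_error_conversion(70, 35)$cycles
```

ADC codes and angles convert by integer floor division in both
directions (`floor(code * 90 / 255)` degrees, `floor(theta * 255 / 90)`
counts).  The PWM stage emits one pulse per stimulation period
($10^6/f$ µs); a new width takes effect at the next period boundary,
never mid-pulse, so no glitch pulses are emitted (the hardware timing
diagrams do not resolve this case; the boundary-latch is this model's
choice).  The dip-switch decoders use ascending code order
(0→70/40/30°, 0→20/30/40/50 Hz) — the wiring is not fixed by the
controller definition, so the mapping is configurable.

## The knee-extension plant

The plant is intentionally generic and fully parameterized
(`plant_params()`): a one-pole activation stage

$$\dot T_a = \frac{G\,pw - T_a}{\tau}$$

maps pulse width to active quadriceps torque, feeding the shank dynamics

$$J\ddot\theta = T_a - mgl\sin\theta - B\dot\theta - K(\theta - \theta_0),$$

with hard stops at 0° and 90° (angle clamped, velocity zeroed on
contact).  The activation stage is advanced by its exact exponential
update; the shank is integrated with fixed-step classical Runge–Kutta at
an inner step of 1 ms under a zero-order hold of the pulse width between
controller samples, with the activation evaluated at mid-step so the
coupled scheme stays second-order accurate (halving the step moves a 5 s
trajectory by well under 0.01°).

**Where the default numbers come from.**  Controllers of this kind are
tuned against a subject-specific musculoskeletal knee model, and that
model is not distributed with this package.  The
defaults shipped in `plant_params()` are therefore this package's own
desk-scale constants, chosen once by construction rather than fitted to
any data:

1. The singleton tables are fixed constants of the controller, so at
   steady state (E ≈ 0, dE ≈ 0) the commanded width is pinned near the ME
   singleton: 380/220/160 µs for the 70°/40°/30° tables.  For the loop to
   settle with a sub-degree error at *all three* references, the static
   load torque $mgl\sin\theta + K\theta$ must pass through those three
   operating points, which forces a load in the ratio 380 : 220 : 160 —
   very nearly linear in angle, i.e. stiffness-dominated.  A
   gravity-dominated load (ratio $\sin 70 : \sin 40 : \sin 30$) cannot
   satisfy all three simultaneously, whatever the gain.  We therefore use
   a small gravitational moment ($mgl = 0.03$ N·m) with a linear
   stiffness $K = 1.2$ N·m/rad about 0° — a linear proxy for the steeply
   rising passive elastic moment of a real knee near extension — and set
   $G = (mgl\sin 70.5° + K \cdot 70.5°_{\mathrm{rad}})/380 \approx
   3.96\times10^{-3}$ N·m/µs, which places the three ME equilibria at
   70.5°, 40.7° and 29.5°.
2. Inertia, damping and activation time constant ($J = 0.9$ kg·m²,
   $B = 2.4$ N·m·s/rad, $\tau = 0.5$ s) were then selected, once, from a
   coarse grid so the transient lands in the plausible clinical regime
   for FES-driven extension — rise times around 2–2.7 s, 2 % settling
   around 3.3–4.2 s, overshoot under 1°, growing with the reference
   angle — and were frozen before being treated as the package default.

Because these constants are constructed rather than published, **every
closed-loop check in this package is a property, never an exact-number
comparison**: the loop must settle within the ±2 % band at each
reference, with steady-state error ≤ 1°, overshoot ≤ 3°, rise and
settling times non-decreasing in the reference angle, and integer-mode
and float-mode metrics within 0.2 s / 0.5° of each other.  Those
properties, not particular seconds and degrees, are what transfers from
the behaviour of the original controller.

```{r, eval = FALSE}
tr <- simulate_closed_loop(70, duration_s = 10, mode = "integer")
step_metrics(tr)
```

## Step-response metrics

`step_metrics()` works on the dense plant trajectory.  Definitions the
source material leaves open are fixed as follows (all configurable where
it makes sense):

* **Rise time**: first crossing of 10 % to first crossing of 90 % of the
  reference, crossings linearly interpolated (the common 10–90 %
  convention; a 0–100 % variant would be dominated by the asymptotic
  tail).
* **Settling time (2 %)**: the *last entry* into the ±2 % band — the
  instant after which the trajectory never leaves it again.  If the final
  20 % of the trajectory is not inside the band the trace is flagged
  `settled = FALSE` instead of being given a time.
* **Overshoot**: $\max(\theta) - \theta_{\mathrm{ref}}$, floored at zero,
  in degrees.
* **Steady-state error**: $|\theta_{\mathrm{ref}} - \bar\theta|$ over the
  final 1 s (a window is needed because the integer loop can dither by a
  quantization step; 1 s averages 10 controller samples).

The closed forms used to validate these definitions (first-order 10–90 %
rise $= \tau\ln 9$, last band exit of a pure exponential $= \tau\ln 50$,
underdamped peak overshoot $= e^{-\pi\zeta/\sqrt{1-\zeta^2}}$) are
evaluated independently in the tests.

`compare_traces()` reports per-sample percentage errors of an integer
trace against its real-valued reference,
$e_i = |r_i - t_i|/r_i \times 100$, each rounded to one decimal before
averaging, excluding zero-reference samples with a warning — the
rounding convention customary in hardware-versus-model comparison
tables (e.g. 43.8 vs 43 → 1.8 %, 12.9 vs 12 → 7.0 %, both exercised in
the tests).

## Synthetic fixtures, and what the tests do not show

`generate_ramp_sweep()` emulates the bench input used to exercise the
controller open loop: a potentiometer swept linearly 0 → 90° and held,
sampled every 100 ms, noise-free by default (optional Gaussian sensor
noise with an explicit seed is available for robustness demonstrations).
The voltage domain is not modelled; fixtures are specified in degrees and
digitized by `angle_to_adc()`.  Only the analytically forced points of
such a sweep (reset, first sample at 0°, saturation at 90°) are exact
anchors; the interior of the original recorded sweep is not public, so
interior values are exercised as properties (bounds, monotonicity,
integer-float agreement) rather than as fixed numbers.

The plant omits muscle fatigue, spasticity, antagonist co-contraction,
day-to-day parameter drift and subject variability — precisely the
phenomena a closed-loop FES controller exists to absorb.  Passing the
closed-loop envelope here shows the integer datapath is a faithful,
stable realization of its design model on a plausible plant; it does not
predict clinical trajectories.

## Problem sizes

The shipped tests and the acceptance script run, by choice: exhaustive
scans of all 256 scaled inputs and all 256×256 input pairs; the
(err, dE) ∈ [−25, 25]² integer-versus-float grid; 10 s closed-loop
simulations (1 ms inner step, 100 ms sampling) at three references in
both controller modes; and cycle-level FSM traces up to ~1.5 s of
simulated time.  All are deterministic.
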