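---
title: "An angular-velocity detector from optomotor building blocks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An angular-velocity detector from optomotor building blocks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(avdu)
```

## The problem

Bees regulate flight — centring in corridors, holding ground speed,
estimating distance flown — from the *angular velocity* (AV) of image
motion, largely independently of the spatial structure of what they see.
The motion detectors actually identified in insect optic lobes are
Reichardt–Hassenstein correlators (RHDs), which are tuned to *temporal
frequency* (AV divided by the pattern wavelength) and therefore confound
speed with spatial frequency. This package implements a mechanistic answer
to how an AV signal can be built from such temporal-frequency-tuned parts:
run two populations of correlators with different delays over the same
retinotopic input, sum each population across the visual field, and read
out the *ratio* of the two sums. The spatial-frequency dependence common to
the two populations cancels in the ratio; what remains grows monotonically
— approximately log-linearly — with AV.

## The model

Every neuron in the model is a rate-coded leaky integrator (LIN),

$$\dot a = \frac{-a + \sum_i x_i}{\tau},$$

with a single time constant. These dynamics are sometimes typeset with
the time constant multiplying, rather than dividing, the drive; we
integrate it as a divisor, the reading under which $\tau$ behaves as a
*time constant* (larger $\tau$, slower unit, longer delay) and under
which the 100 ms smoothing stage is stable at the 0.1 ms step. The
multiplicative reading remains available
(`avdu_params(tau_divisor = FALSE)`) for comparison.

One **angular-velocity detector unit** (AVDU) spans two neighbouring
visual locations:

1. **Adaptive photoreceptor stage** (per location). A LIN with a
   subtractive adaptation current, $\dot a_{PR} = (-a_{PR} - \alpha + x)/
   \tau_{PR}$, $\dot\alpha = (-\alpha + x)/\tau_\alpha$, with
   $\tau_{PR} = 8$ ms and $\tau_\alpha = 15$ ms. Under constant light
   $\alpha \to x$ and $a_{PR} \to 0$: the stage is a pure
   luminance-change detector with zero DC gain (this is tested as an
   invariant).
2. **Rectification.** Spiking neurons after the lamina cannot carry signed
   signals, so the photoreceptor output is rectified; the default keeps
   luminance *offsets* only (`rect_mode = "offset_only"`), the variant the
   response curves select as most log-linear. Onset-only, full and no
   rectification are available for comparison.
3. **Two correlator subunits** (fast and slow). Each correlates a direct
   channel (LIN, $\tau_b = 1$ ms) at one location with a delayed channel at
   the other. The delay is either *dynamic* — a LIN with $\tau_1 = 5$ ms
   (fast subunit) or $\tau_2 = 15$ ms (slow), distorting as it delays — or
   *fixed* — a pure sample delay $d_1/d_2$ followed by a $\tau_b$ LIN.
   Preferred-direction (progressive) and anti-preferred (regressive)
   products are combined as $\mathrm{prog} - F\cdot\mathrm{reg}$ and
   filtered by a subtraction LIN ($\tau_R = 5$ ms). $F = 1$ gives the
   classical fully opponent correlator; the default $F = 0.25$ trades
   opponency for spatial-frequency invariance of the final ratio.
4. **Array readout.** Fast and slow subunit outputs are summed separately
   across all detectors of an array; the ratio
   $\mathrm{sum_{fast}} / \max(\mathrm{sum_{slow}}, 0.01)$ — the fast
   (small-delay) subunit is always the numerator — drives a smoothing LIN
   ($\tau_S = 100$ ms) whose activity $S$ is the AV estimate. Only the
   denominator is floored (a stand-in for tonic firing), so $S$ can go
   negative. Whether the division precedes or follows the smoothing is a
   genuinely open wiring choice; we divide first and smooth the ratio
   (`ratio_order = "divide_then_smooth"`), with the other order available
   as a flag.

Integration is forward Euler at $dt = 0.1$ ms throughout, all state zero
at $t = 0$. Within a step the stages update in feedforward order, each
seeing its upstream stage's freshly updated activity; the suite checks
step-halving convergence (< 1% over 2 s) and agreement of the compiled
stepper with two independent R implementations to machine precision.

## Measurement rigs

The **test system** is a flat 100 x 2 grid of point receptors at 2°
spacing (198 AVDUs, one shared readout) stimulated by drifting square or
sine gratings; every response is the time-mean over the final second of a
2-s run from zero state. `sweep_av()` reproduces the AV tuning curves,
`sweep_tf_subunits()` the pre-division correlator tuning curves that are
compared with optomotor neurons, `fit_forms()` the
linear/logarithmic/exponential model comparison by adjusted $R^2$
(exponential via OLS on $\log y$, with an optional `nls` refinement).

The **full system** samples a box corridor (20 cm wide, matching the
behavioural corridors; height 20 cm and length 300 cm are our choices,
as only the width is constrained) through a 32 x 32
equirectangular grid of single rays spanning 260° x 180°. Three AVDU
arrays sit on this grid — left and right lateral bands (rows 9–14 from the
bottom, 11 AVDUs per row) and a ventral band (rows 1–6, 5 AVDUs per
column) — each preferring motion away from the frame centre and feeding
its own smoothed readout $S_L$, $S_R$, $S_C$. A 13-column right-hand band
(columns 20–32) would wire 12 detectors per row, contradicting the
11-per-row layout the subregions are defined by; we use columns 21–32,
the exact mirror of the left band.

A flight controller turns the readouts into pose updates every 10 ms:
$\Delta X = \mathrm{sgn}(S_L, S_R)(\max(S_L,S_R) - T_X)/2.4$,
$\Delta Z = (S_C - T_Z)/18$, $\Delta V = -(S_L + S_R - T_V)/2.4$ with
$T_X = 1$, $T_Z = 0.5$ and $T_V = 2T_X$ (the velocity setpoint is taken
as twice the horizontal one). Applying the deltas at the 0.1 ms neural
step with these divisors would command accelerations of order
10^3 m/s², so a 10 ms control interval is used and exposed in the
configuration. `sgn` treats differences below 1e-9 as ties: in a
perfectly symmetric corridor the two array sums differ only by
floating-point summation order, and a strict sign would let that noise
pick a lunge direction. Trials begin with a 1-s open-loop warm-up in
which the bee coasts while the detector states charge (the smoothing
stage alone needs several hundred ms); engaging the controller against
uncharged detectors ($S \approx 0$) produces a large spurious lateral
command. Corridor wall/floor patterns are quoted in cycles/degree as seen
from the corridor centre, at one fifth of the bee-scale values (the model
eye has one fifth the bee's resolution); the floor carries a 0.1 c/deg
(bee-scale) square wave so the ventral band receives optic flow. The
corridor pattern repeats indefinitely along the axis, so trials never run
out of world.

```{r example}
params <- avdu_params()
curve <- sweep_av(params)             # AV tuning, 10-1000 deg/s
fit_forms(curve)                      # logarithmic form wins
world <- corridor_world(
  left_wall = wall_pattern("sine", scale_spatial_frequency(0.15)),
  right_wall = wall_pattern("sine", scale_spatial_frequency(0.3)))
traj <- run_trial(world, build_full_system(params))
final_offset(traj)                    # mean lateral offset, final 2 s
```

## What the synthetic world does and does not establish

All inputs are synthetic and deterministic: gratings with exactly known
wavelength, velocity and contrast, and an idealised corridor with
noise-free single-ray sampling. A green test therefore establishes the
*internal* consistency of the model — its tuning, invariances and
closed-loop consequences under this geometry — not agreement with
physiological recordings (no electrophysiological data ship with or are
refit by this package) nor robustness to photon
noise, natural scenes, or body dynamics (no aerodynamics, saccades or yaw;
the pose is clamped inside the corridor walls with a 0.5 cm margin and
speed floored at zero).

Two renderer simplifications matter when interpreting corridor results.
First, the renderer is a deliberately minimal equirectangular single-ray
projection, not a full ray-traced eye model; with it, wall patterns
compress in azimuth away from abeam and exceed the 8.125° sampling
Nyquist limit well before the finest behavioural frequencies, so
high-frequency conditions carry aliased motion information. Second, point
sampling (no acceptance-function blur) sharpens that aliasing. Under
these simplifications the corridor detector gain at the prescribed
40 cm/s start sits below the controller setpoints, so closed-loop flights
spend several seconds accelerating and wall-following before the centring
equilibrium (max of the lateral readouts equal to $T_X$) becomes
attracting: equal-wall trials end farther from the centre than real bees
do, and the deviation-versus-frequency pattern is dominated by which wall
remains resolvable rather than by the graded frequency ordering seen in
bees. The acceptance suite asserts the behavioural envelopes and reports
these conditions as failures rather than relaxing them; the unit suite
pins down the mechanisms that do hold (exact mirror symmetry of the
closed loop, symmetric worlds centring exactly, the controller's fixed
points).

## Numerical and design notes

- **Readout scale.** The division operates on raw array sums.
  With 198-detector sums the 0.01 denominator floor engages
  only for near-silent arrays; we verified that the alternative
  (per-detector means, floor at per-neuron scale) restores some reversal
  suppression but destroys mid-AV contrast invariance — the floored ratio
  scales with contrast squared — and flattens nothing else of value, so
  the literal contract is kept.
- **Direction selectivity of the ratio.** Each correlator subunit is
  direction selective (its response drops under motion reversal; unit
  tested), but at $F = 0.25$ the slow subunit suppresses *more* than the
  fast one, so the fast/slow ratio itself rises under reversal. Full
  opponency ($F = 1$) makes reversed $S$ negative. The behavioural
  invariance report prints the measured reversal ratio rather than
  asserting a suppressed one.
- **Subunit tuning peak.** The pre-division tuning curves peak in the
  low-teens of Hz on the default grid rather than exactly at 10 Hz; the
  location is insensitive to halving $dt$ and to contrast, and none of
  the model's parameters moves it. The acceptance script reports the median peak over
  both subunits and all three wavelengths, computed fresh each run.
- **Equal-delay limit.** With $\tau_1 = \tau_2$ the two subunit sums are
  identical, so wherever the denominator clears the floor the ratio is
  exactly 1 (flat). Below that — low AV, weak responses — the floored
  ratio follows the rising numerator, so the sweep is flat only above the
  floor-crossing AV. The parameter validator allows $\tau_1 = \tau_2$ for
  exactly this diagnostic.
- **Degenerate inputs.** Contrast-0 stimuli give $S = 0$ via the floored
  `0/0.01`; empty layouts give zero detectors and $S \equiv 0$; a
  zero-distance trial makes the odometry metric error rather than return
  `Inf`; a non-finite detector output aborts a trial with the time of
  failure.
- **Centering agreement is sign/rank only.** Behavioural deviation
  magnitudes are figure readings, so `assess_centering_pattern()` scores
  the direction of deviations and their Spearman rank correlation with
  the log wall-frequency ratio (thresholds 0.75 and 0.8); the assessment
  is invariant to any positive rescaling of the offsets, and a test
  enforces that invariance.
- **Odometry.** $D_E = \sum_t (S_L + S_R)/D$ is summed at control
  resolution; $D$ is the along-corridor path length (speed is
  non-negative, so this equals the net displacement).

## Known limitations

The corridor-level quantitative claims (centring envelope, deviation
ordering, odometry constancy to 0.6 c/deg) are sensitive to the effective
detector gain the eye model delivers, which the minimal renderer here
does not match to the behavioural data; its corridor results should be
read as the behaviour of *this* simulated world. The test-system claims
(log-linear AV response,
best-fit model selection, contrast and wavelength invariance, delay-pair
ordering, rectification comparison) are insensitive to the renderer and
reproduce cleanly.
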