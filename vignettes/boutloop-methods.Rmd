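---
title: "Models and methods behind boutloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind boutloop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boutloop)
```

`boutloop` packages the computational machinery of closed-loop optomotor
experiments in larval zebrafish: the virtual assay, a delayed
feedback-controller model of bout generation, the offline behavioral and
calcium-imaging analyses, and synthetic-data generators that make every
stage testable. This vignette records the models, the tunable parameters,
and the numerical and design choices, in enough detail that a reader can
judge what the passing test suite does and does not establish.

## The closed-loop assay

The assay estimates the forward velocity a head-restrained larva would
reach from its tail kinematics. *Vigor* is the sliding standard deviation
of the cumulative tail angle over a trailing 50 ms window, computed
causally as on a real-time rig (`compute_vigor`; the population form of
the SD, so a fast oscillation of amplitude $A$ plateaus at $A/\sqrt2$).
A session-specific multiplier maps vigor to velocity such that the median
estimated velocity over in-bout samples is 20 mm/s, the speed of a freely
swimming larva (`calibrate_multiplier`); samples above 2 mm/s count as
in-bout online (`detect_bouts_online`, strict inequality, no hysteresis —
refined segmentation happens offline).

Reafference conditions transform the estimated velocity $v(t)$ into the
grating velocity shown on top of the base command $u_0$ (10 mm/s forward
during trials):

* **gain** $g$: $u(t) = u_0 - g\,v(t)$ during bouts; $g \in \{0, 0.33,
  0.66, 1, 1.33, 1.66, 2\}$. Gain 0 is open loop, gain 1 normal
  reafference.
* **lag** $L \in \{0, 75, 150, 225, 300, \infty\}$ ms: the gain-1
  reafference stream is delayed by $L$; non-shunted, it persists exactly
  $L$ past bout offset (the source of "excessive reafference after the
  bout"), shunted it is cancelled at offset.
* **gain drop**: the first 300 ms of each bout are divided into four
  75 ms segments whose gains are a binary profile (e.g. `1100`); gain is
  1 beyond 300 ms, matching the resumption of normal reafference.

Several battery entries induce identical mappings. `enumerate_conditions`
establishes the equivalence classes *functionally*: every entry is applied
to a probe trace containing one constant-velocity bout with a long quiet
tail, and entries with identical outputs merge. The 27 battery entries
collapse to 18 conditions; profiles `0111/0011/0001/0000` coincide with
the shunted lags 75/150/225/300 ms, and `{gain 0, lag ∞}` and
`{gain 1, lag 0, profile 1111}` form the open-loop and normal classes.

Protocols share one trial: 7.5 s static, 15 s forward motion, 7.5 s
static. Phase layouts are 10/10/210/10 trials (acute reaction: per-bout
conditions drawn uniformly from the 18; long-term adaptation: all
adaptation bouts at 225 ms non-shunted lag for lag-trained fish),
10/10/50/50 (Purkinje-cell imaging) and 120 s blank + 10/10/40 with
normal/open-loop bouts and paired 350 ms reverse pulses in the static
periods (whole-brain imaging). Per-bout draws use a seeded RNG: condition
assignment happens at bout onset, uniformly over the unique set (no
weighting is assumed for the acute protocol, and uniform rather than
stratified sampling — the simpler reading).

## The feedback-controller model

The controller never predicts its own reafference; it only reacts to the
delayed visual consequence of swimming. Its input is the shown grating
velocity $u(t - \Delta t)$ with a fixed $\Delta t = 220$ ms sensory
processing delay. Each 5 ms step applies, in order:

$$s_{\mathrm{in}} = \omega_f \max(u, 0) - \omega_r \max(-u, 0)$$
$$\tau_s \dot V = -V + s_{\mathrm{in}}, \qquad V \in [0, 1]$$
$$D = \max(0,\; V + \omega_s b_{\mathrm{prev}} - \omega_i M), \qquad
  b = \mathbb 1[D \ge thr]$$
$$\tau_m \dot M = -M + \omega_m b, \qquad M \le 1, \qquad
  v_{\mathrm{out}} = 20\,b \;\mathrm{mm/s}$$

$V$ is the sensory drive ("motivation to swim"), $M$ the tiredness that
guarantees finite bouts under sustained drive, $\omega_s$ a
self-excitation loop that keeps bouts alive when reafference suppresses
$V$ right after onset. Eight parameters are free; $\Delta t$ and the
20 mm/s output are fixed.

Numerical choices:

* **Exponential-Euler discretization**, $x \leftarrow x e^{-dt/\tau} +
  w\,u\,(1 - e^{-dt/\tau})$ at $dt = 5$ ms. It is unconditionally stable
  and *exact* for piecewise-constant input; for time-varying input the
  global error is first order in $dt$ (the suite verifies < 1% at 5 ms
  against the closed-form linear-ODE solution, shrinking roughly
  linearly with $dt$).
* The threshold comparison uses the *previous* step's bout flag inside
  the self-excitation term — this is the hysteresis that sustains bouts.
* The delay buffer is primed with the trial's initial (static) command,
  so trial starts are well defined; the controller state resets between
  trials (trials are separated by 15 s of static grating, several times
  every model time constant).
* Sign convention: forward grating motion is positive; reafference from
  swimming makes the input negative and engages the inhibitory
  $\omega_r$ path.
* The linear forms above (the drive entering the motor generator
  additively, the motor integrator weighting its input before the leak)
  are one concrete reading of a leaky-integrator controller; they are
  isolated in a single compiled update so alternates are swappable.

The in-loop reafference scheduling (including lagged streams crossing
bout boundaries and shunted cancellation) is implemented once in the
compiled core and once, vectorized, in `apply_reafference`; a test pins
the two against each other on whole sessions.

**Reference parameters.** `reference_params()` is the package's canonical
operating point: ω_f = 0.19, ω_r = 0.058, τ_s = 1.65 s, thr = 0.40,
ω_s = 0.66, ω_m = 0.90, τ_m = 0.95 s, ω_i = 2.5. It was found by a seeded
random search over the fitting bounds, scored on (i) producing an output
(a third bout in the model test trial) for all 18 conditions, (ii) the
full qualitative acute-reaction ordering suite — open-loop bouts longer
than normal and high-gain bouts; interbouts longer at both gain extremes
than at gain 1; bout duration non-decreasing in lag; interbouts longer
after non-shunted than shunted 300 ms lag; early gain drops prolonging
bouts more than late ones; late gain drops shortening interbouts more
than early ones — and (iii) realistic normal-reafference durations
(bout ≈ 400 ms, interbout ≈ 675 ms, ≥ 5 bouts per 15 s trial). The
orderings emerge from the interplay the model is built around: weak
reverse weight and a slow velocity integrator let mild reafference dent
the drive only partially (so stronger reafference depletes it more and
lengthens the next interbout), while tiredness accumulated over very long
open-loop bouts dominates the high drive and prolongs the interbout from
the other side of the V.

## Fitting

`fit_controller` minimizes the mean absolute error between the model's
36-value summary (bout and interbout durations over the 18 conditions,
from the short model test trial: 300 ms static + 9.7 s forward motion,
first bout normal, second bout probed, output only if a third bout
starts) and a target summary, each entry normalized by the target.
Conditions for which the model produces no output contribute a fixed
pessimistic penalty of 2.0 — the real analysis silently drops such
trials, but an optimizer needs a finite value.

The optimizer is a plain generational GA — population 64, tournament
selection (k = 3), uniform crossover (p = 0.5), per-gene Gaussian
mutation (σ = 10% of the bound range, p = 0.2), 2 elites, 200
generations — with time constants searched in log space over
[0.05, 20] s, weights over [0.001, 10] and the threshold over
[0.01, 1]. The objective, not the optimizer, is normative: any
derivative-free method reaching the recovery property (train MAE ≤ 0.05
when fitting a known parameter set's table) is equivalent. Parameter
*identifiability* is deliberately not promised — distinct parameter sets
can produce near-identical duration tables; the recovery tests therefore
assert behavior, not parameters. `split_durations` provides the
per-condition 50/50 train/test split (odd arrays give the extra
observation to the training half).

## Behavioral analysis

Offline analysis works on a 5 ms grid (tail traces z-scored session-wide;
the raw-radian trace is kept because bout power is measured in rad²).
A *flick* is the section of the tail trace between adjacent local extrema
with magnitude > 0.14 rad and duration ≤ 100 ms; extrema are defined with
strict comparisons and plateaus take their first sample, so boundaries are
deterministic. Online bout intervals are snapped to the first/last
qualifying flick; bouts outside forward grating motion, shorter than
100 ms, or adjacent to an interbout shorter than 100 ms are excluded
(neighbouring interbouts are measured before exclusion). The interbout
after a trial's last bout is undefined. Animals with ten consecutive
boutless trials are excluded outright.

Bout power selects 1.1 s of the tail trace from 100 ms before onset — the
half-open window [-100, 1000) ms holds exactly 220 samples at 5 ms —
subtracts the median of the pre-onset 100 ms, zeroes samples after bout
offset, and squares. Per-timepoint Kruskal–Wallis tests across conditions
use a Bonferroni threshold of 0.05/220. The ballistic/reactive boundary
sits at 220 ms after onset — the sensory delay — and areas under the
power curve are trapezoidal (the reactive area integrates to 995 ms, the
last grid point of the window).

Block metrics average a per-trial value (canonically first-bout duration)
over blocks of ten trials, skipping trials without a value: acute
reaction = first ten adaptation trials − pre-adaptation; reduction = last
ten − first ten adaptation trials; after-effect = first ten
post-adaptation − pre-adaptation. A lag-trained fish is *adapting* when
its first-bout duration falls by ≥ 40 ms across the adaptation phase.
Group comparisons use the Mann–Whitney U test as implemented by
`stats::wilcox.test` (exact for small untied samples, normal
approximation with tie correction otherwise); all-tied input returns
p = 1 with a warning rather than an error.

## Imaging analysis

Traces are detrended with 4th-order zero-phase Butterworth filters:
whole-brain mode low-passes at 0.56 Hz (the frequency corresponding to
the 1.8 s GCaMP6s half-decay) and subtracts a 3.3 mHz low-pass baseline;
Purkinje-cell mode high-passes at 3.3 mHz; both z-score afterwards.
`signal::filtfilt` is applied after odd-reflection padding of roughly
three filter time constants — without it, edge transients of the very
long 3.3 mHz impulse response dominate the first and last few hundred
samples. The idempotence property (re-preprocessing changes the trace by
< 1%) accordingly holds on the interior of a trace for signals whose
energy sits below the de-noising cutoff.

Triggered averages use 5 s windows starting 1 s pre-trigger (2.2 s for
the Purkinje first-bout windows); triggers with another trigger in the
preceding second are dropped, later triggers inside a window mask the
remainder with NaN, and the pre-trigger mean is subtracted. Sensory and
motor scores are the means of the grating-/bout-triggered averages over
0–4 s and 0–2 s; their nulls come from cutting the trace into 23 s
sections and shuffling the sections 1000 times (the section count derives
from the trace length rather than being fixed, so the null generalizes to
synthetic sessions; free rather than circular reordering is used).
Significance is the 95th percentile; a unit is *sensory* if its sensory
score is significant and *motor* only if its motor score is significant
while the sensory one is not — in closed loop nearly every sensory unit
also carries motor-locked signal, and with a deterministic behaver the
confound is maximal, so the suite asserts the sensory priority rule and
type-I control, not motor-unit recall.

Time constants are estimated by forward-modelling the fluorescence as the
leaky-integrated, forward-rectified shown grating velocity convolved with
an exponential indicator kernel (1.8 s half-decay), scanning τ over
0.5–10 s in 0.5 s steps and keeping the correlation argmax; τ ≤ 1.5 s is
a *sensor*, larger an *integrator*. The full shown-grating input (which
already reflects reafference) is used, forward-rectified; bout periods
are not excised. Changes across adaptation are per-unit differences of
block-wise τ, smoothed for display with a 0.1 s kernel and flagged below
−0.4 s.

ROI segmentation computes a correlation map (each voxel against the mean
of its eight in-plane neighbours — border voxels use the neighbours that
exist), then grows ROIs from the highest unassigned map value ≥ 0.3,
adding 8-adjacent voxels whose correlation with the ROI's mean raw trace
exceeds a threshold ramping 0.30 → 0.35 over 3 µm of in-plane Euclidean
distance from the seed. ROIs outside 9–28 µm² are discarded with their
voxels marked assigned (this, not the seed threshold, is what rejects
chance clusters in white noise). Traces are voxel sums.

The Purkinje-cell barcode converts four block-difference criteria (first
ten adaptation − pre; last − first ten adaptation; first ten post − last
ten adaptation; last − first ten post, computed from mean
first-bout-triggered fluorescence 0–1.2 s after onset) into symbols by a
trial-permutation null: non-calibration trials are shuffled jointly for
all four criteria (one permutation yields one draw of each), 100,000
times by default; above the 97.5th percentile is `+`, below the 2.5th
`-`, else `0`. Because the permutation null inherits the *planted signal
variance*, detectability is governed by the criterion step size relative
to the per-trial noise; the synthetic barcode generators therefore define
SNR as step/noise-SD. Under exchangeable responses the four criteria are
mutually correlated (they share blocks), so the probability of the
all-`0` barcode exceeds the 0.815 independence bound — empirically ≈ 0.85
for the 120-trial layout. Cluster enrichment compares within-fish barcode
fractions across groups with Kruskal–Wallis at 5%, reporting clusters
whose mean fraction reaches 2% in some group.

## Synthetic data

The generators emulate the statistical structure each analysis assumes,
and always emit their ground truth:

* **Tail sessions**: bout timing comes from a behaver — the controller
  (default), a scripted schedule, or a custom causal callback — run in
  closed loop with per-bout conditions drawn per protocol. Bouts are
  rendered as a 25 Hz cosine carrier (the larval tail-beat scale) of
  0.5 rad amplitude under a rectangular envelope: the carrier starts at
  an extremum, so the first qualifying flick begins exactly at the
  ground-truth onset and flick-corrected segmentation recovers durations
  to within two grid steps. A tapered envelope and sensor noise are
  available (`env_ramp_s`, `tail_noise_sd`) but default off; real bouts
  taper and real traces are noisy, so segmentation accuracy on real data
  will be somewhat worse than the tests show.
* **Cohorts**: adapting lag-trained fish drift their controller
  parameters linearly over the adaptation phase toward an "adapted" set
  (ω_m × 1.25, ω_i × 1.1 — a stronger tiredness pathway) that persists
  through post-adaptation, emulating an internal model recalibrating the
  controller (the long-term change is located in the controller, not the
  environment). Non-adapting fish keep fixed parameters with sensor
  weights blunted by 15%; controls keep normal reafference. Small
  lognormal per-fish jitter (CV 2%) provides between-animal variability;
  within-fish trial-to-trial noise is absent because the controller is
  deterministic, which makes the cohort's group tests easier than with
  real fish — the suite checks sign structure and rejection, not effect
  sizes.
* **Fluorescence**: latent signals (leaky-integrated stimulus for
  sensors/integrators, the bout flag for motor units, per-trial
  first-bout impulses with a stepped amplitude schedule for barcode
  units) convolved with the indicator kernel, unit-SD scaled, plus
  Gaussian noise (SD = 1/SNR) and one slow sinusoidal drift (period
  600 s) so detrending efficacy is measurable. The barcode amplitude
  schedule holds each half of the adaptation and post phases at its
  block level, so the intended criteria are exact by construction.
* **Volumes**: flat discs of radius 1.8 µm (≈ 10 µm², inside the somata
  bounds) sharing a smooth within-blob time course at a chosen SNR on
  unit-variance white background, placed with a minimal separation.
  Photon statistics, motion and anatomical structure are not modelled.

## Problem sizes and limitations

The shipped tests run synthetic sessions of a few trials per phase,
cohorts of 2–20 fish per group, 100-unit τ-recovery ensembles, 150-unit
barcode nulls at 10,000 shuffles, and single-plane 48×48×120 volumes —
sizes chosen so the whole suite completes in about two minutes while
every statistical check retains a comfortable margin. What passing shows:
the implementations agree with their independent oracles, invariants and
printed constants, and recover planted structure at the stated SNRs. What
it does not show: performance on real recordings with tapered bouts,
tracking noise, non-stationary baselines, correlated neuropil, or
behavioral variability beyond the parameter-jitter model; and the
Mann–Whitney/Kruskal–Wallis calls inherit `stats`' tie handling rather
than reimplementing the exact references used by any particular lab.

Registration, atlas mapping, spike deconvolution and real-time tracking
are out of scope. Recordings serialize to flat CSV with a commented
header, protocols and fits to JSON; the exported functions are the
interface, and every stochastic step takes an explicit seed and is
bit-reproducible under it.
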