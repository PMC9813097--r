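---
title: "Methods: simulating and quantifying homeostatic OKR plasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and quantifying homeostatic OKR plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(okrplast)
```

## The scientific problem

The optokinetic reflex (OKR) is the visuo-motor reflex that rotates the
eyes to follow large-field visual scene motion. In larval *Xenopus*,
prolonged (30 min) oscillatory visual motion entrains the OKR: animals
with large initial response amplitudes end up with smaller ones, and
animals with small initial amplitudes end up with larger ones. Plotting
each animal's training-induced amplitude change
$\Delta = E - I$ against its immediate amplitude $I$ (both in degrees,
peak-to-peak) reveals a linear relationship

$$\Delta = m\,(I - x_0),$$

whose slope $m$ quantifies how strongly the plasticity depends on the
initial performance and whose x-axis zero-intercept $x_0 = -b_0/m$ (the
*setpoint*) is the amplitude at which training induces no net change.
This is the signature of a homeostatic mechanism that pulls the motor
output towards a preset magnitude. In mature animals the pull is
bidirectional (strong slope, setpoint in the middle of the amplitude
range); in young animals, and in animals whose climbing-fiber input to
the cerebellum has been transected, amplitude increases are absent and
the fitted setpoint collapses towards zero.

`okrplast` implements the complete measurement chain for this analysis —
stimulus construction, eye-movement simulation (and phantom-video
tracking), per-cycle amplitude extraction, and the setpoint regression
with its accompanying nonparametric statistics — plus the serial-section
volume morphometry used to compare cerebellar maturity between ages.

## The synthetic cohort generator

No raw per-animal recordings are publicly deposited for this paradigm,
so the package ships a first-class generator that emulates the study's
cohorts from the summary statistics that are published.

**Stimulus.** A session is a triangular position waveform of constant
absolute velocity: `stimulus_profile(id)` with the four standard
paradigms (4 or 8 deg/s crossed with 20 or 10 s cycle duration; 30 min
total). The peak-to-peak excursion of a half cycle is
$v \cdot T / 2$ — 40 deg for the 4 deg/s / 20 s reference profile. The
waveform starts at its positive extremum, so cycle boundaries are the
analytically known extremum times $kT$.

**Per-cycle plasticity rule.** Each animal carries a latent initial
amplitude $I$ ($A_0 = I$) and relaxes geometrically towards a target
$x_0$:

$$A_k = A_{k-1} + \rho\,(x_0 - A_{k-1}) + \varepsilon_k,
\qquad \rho = 1 - (1 + m)^{1/K},$$

with $K$ the number of cycles in the session. The retention rate
$\rho$ is defined so that the noise-free session-end amplitude is
exactly $(1+m)I - m x_0$ — the linear $\Delta$-vs-$I$ rule — while the
relaxation produces the rapid early amplitude decrease seen in per-cycle
population averages. The per-cycle noise $\varepsilon_k$
(`gain_noise_sd`, default 0.1 deg) accumulates as a mean-reverting
random walk with stationary SD $\approx$ `gain_noise_sd`$/\sqrt{2\rho}$;
at the session scale this contributes roughly 0.7-1.6 deg of
cycle-to-cycle wander, comparable to real per-cycle amplitude traces.
Amplitudes are floored at zero, their physical lower bound.

**Group presets.** `okr_group_params()` carries the published group
rules (old: $m = -0.59$, $x_0 = 6.4$ deg; young: $-0.48$, $0.6$ deg;
climbing-fiber-transected: $-0.29$, $0.94$ deg), and
`okr_cohort_design()` the per-paradigm cohort sizes and pre-training
amplitude distributions. Initial amplitudes are drawn from a normal
distribution truncated below at 0.5 deg (only a mean and SD are
published). Two generator choices deserve comment:

* *Young initial amplitudes.* Per-paradigm pre-training distributions
  are published only for the old cohort; the young cohort reuses them.
  The setpoint regression is invariant to the shape of the
  $I$-distribution, so this choice does not move the recovered
  parameters.
* *Animal-level residual.* Real cohorts scatter about the regression
  line far more than the per-cycle noise explains. The generator adds a
  per-animal perturbation of the relaxation target,
  $x_{0,i} = x_0 + \eta_i$ with
  $\eta_i \sim N(0, \sigma_\mathrm{res}/|m|)$, which makes the
  session change carry an additive $N(0, \sigma_\mathrm{res})$ residual.
  The defaults ($\sigma_\mathrm{res}$ = 1.8 deg old, 3.5 deg young,
  1.0 deg transected) were set by closed-form variance propagation so
  that the pooled regression reproduces the published $R^2$ where one is
  published (0.765 old, 0.378 young); the transected group's value is
  proportional to the old group's residual relative to its
  initial-amplitude spread. The target is deliberately *unbounded*: a
  negative target simply relaxes the amplitude towards its physical
  floor of zero (see "Known limitations").

**Recording realism.** Eye traces are triangular waves phase-locked to
the stimulus with amplitude $A_k$ in cycle $k$; the two eyes are
conjugate up to independent per-frame noise (0.05 deg SD, the precision
of a good sub-pixel ellipse fit); timestamps are ~30 fps with 3 ms
Gaussian jitter; fast phases (rapid resetting eye movements) are
injected as half-sine conjugate pulses of 5-15 deg completing within
100 ms, at 0.2 events/min ("infrequent" in the original protocol).

## Eye tracking from phantom videos

`render_frames()` draws each video frame as two filled dark ellipses on
a light background, long axes rotated to the ground-truth eye angles.
The tracker (`segment_eyes()`, `fit_ellipse()`, `track_eyes()`)
reproduces the published measurement: per frame, each eye's region of
interest is thresholded (Otsu), the largest dark connected component is
kept, and the orientation of the ellipse — the angle between its long
axis and the horizontal image axis — is computed from second-order
central image moments,

$$\theta = \tfrac{1}{2}\,\mathrm{atan2}\!\left(2\mu_{11},\;
\mu_{20} - \mu_{02}\right) \in (-90, 90],$$

counterclockwise-positive with the y-axis taken upward. Moment-based
orientation was chosen over boundary least-squares because it is robust
on filled masks and has an exact small-case oracle. Near-circular masks
(axis ratio < 1.2) have no meaningful orientation and are flagged
rather than trusted. Orientation series are unwrapped by choosing the
±180 deg-equivalent angle closest to the previous valid frame, so
crossing +90 deg produces no artificial jump. On rendered phantoms with
axis ratio ≥ 1.5 the full render-track loop recovers the generator
angles with RMSE < 0.5 deg.

## From raw traces to per-cycle amplitudes

`process_recording()` applies, in order:

1. **Resampling and filtering** (`resample_filter()`): linear
   interpolation of the irregularly sampled series onto a uniform
   200 Hz grid, then a 4 Hz low-pass Butterworth filter of order 4
   applied forward-backward (zero phase). Zero phase matters because
   cycle segmentation is timing-sensitive; the forward-backward pass
   squares the magnitude response, leaving the 0.05-0.1 Hz stimulus
   fundamentals attenuated by far less than 2% while suppressing a
   10 Hz disturbance below 1%. Edge transients are removed by
   odd-reflection padding. One numerical note: the filter rounds the
   triangular waveform's sharp apexes (the harmonic tail above ~3 Hz),
   scaling measured peak-to-peak values uniformly by ~0.990-0.995
   depending on the cycle period. The scaling cancels exactly in the
   regression slope and rescales the setpoint by the same factor; it is
   a property of the published filtering protocol and is not corrected
   for.
2. **Conjugate averaging** (`conjugate_average()`): sample-wise mean of
   the two eyes in the shared sign convention. A single missing eye
   falls back to the other with a warning; anticorrelated eyes (a sign
   convention error) also warn. Averaging commutes with the linear
   filter, so it is applied first for speed with identical results.
3. **Cycle segmentation** (`segment_cycles()`): boundaries at the
   analytically known stimulus extrema (full period, positive extremum
   to positive extremum), not detected from the recorded stimulus —
   deterministic and jitter-proof. Partial leading/trailing segments
   are flagged `edge`.
4. **Artifact exclusion** (`detect_artifact_cycles()`): a cycle is
   invalid when peak absolute eye velocity exceeds
   `max(20 deg/s, 3 x stimulus speed)` — an automated surrogate for
   the original study's manual identification of fast-phase and jerk
   cycles (both thresholds configurable). Acquisition gaps longer than
   0.5 s invalidate overlapping cycles.
5. **Amplitude extraction** (`cycle_amplitudes()`): peak-to-peak
   (max - min) of the conjugate trace per cycle window.

Whether a "cycle" spans a full period or a half period is not fully
determined by the protocol text; the full period was chosen, matching
peak-to-peak segmentation of a triangular stimulus.

## The plasticity statistics

`immediate_entrained()` averages the first and last five *valid* cycles
(skip-and-extend across excluded cycles) into $I$ and $E$;
`regress_change()` fits $\Delta = E - I$ against $I$ by ordinary least
squares, pooled across stimulus paradigms (a single line per group, as
the original analysis plots it), and reports slope, $R^2$, the setpoint
$x_0 = -b_0/b_1$ (declared undefined when $|b_1| < 10^{-6}$ rather than
reported as a huge number), and a 95% confidence band. Unit-scale
equivariance holds exactly: rescaling all amplitudes by $c$ leaves slope
and $R^2$ unchanged and scales $x_0$ by $c$. The regression is of
$\Delta$ on $I$ as plotted, not $E$ on $I$ re-expressed.

Group comparisons use the two-sided nonparametric tests of the original
analysis: Wilcoxon signed-rank for paired data (exact by full
enumeration of sign assignments up to 12 nonzero pairs — enumeration
handles tied ranks, which closed-form exact routines refuse),
Mann-Whitney U for unpaired data (exact for combined n ≤ 12 without
ties), and Kruskal-Wallis with tie correction followed by Dunn's
pairwise z-tests. The Dunn correction is Bonferroni; sidedness and the
multiple-comparison flavour are not stated in the original methods, so
two-sided and Bonferroni were chosen as the most conservative standard
pairing.

## Parameter recovery and its expected small biases

`recover_group()` runs the full pipeline end to end on seeded synthetic
cohorts at the published cohort sizes (37 old, 28 young, 15 transected)
and refits the regression, by default over 20 replicates;
`summarize_recovery()` averages the replicates. Three systematic effects
are worth knowing about, all small and all documented consequences of
the measurement chain rather than tunable knobs:

* *Edge-window attenuation.* $I$ and $E$ are five-cycle means, not
  instantaneous values, so the recovered slope is attenuated slightly
  towards zero (about $-0.577$ recovered for a generating $-0.59$).
* *Setpoint averaging.* The per-replicate ratio $-b_0/b_1$ is
  heavy-tailed: a single near-flat replicate can place its zero
  crossing arbitrarily far out. The replicate summary therefore reports
  the zero crossing of the replicate-averaged line,
  $-\overline{b_0}/\overline{b_1}$, with a leave-one-out jackknife
  Monte-Carlo SE — a consistent and stable average of the fitted lines.
* *Nonnegativity censoring.* Amplitudes cannot be negative. When the
  animal-level residual is large relative to the setpoint (the young
  group: 3.5 deg of scatter about a 0.6 deg setpoint), the linear rule
  predicts negative entrained amplitudes for a tail of animals
  (~15% young); their measured amplitudes are censored at ~0 and the
  recovered setpoint is biased upward by several tenths of a degree
  (young cohorts recover ~1-1.5 deg). This tension is intrinsic: no
  generative model with homoscedastic Gaussian residuals of the
  published magnitude can produce strictly positive amplitudes around a
  near-zero setpoint. Recovery tests therefore use Monte-Carlo
  tolerances (3 SE over 20 replicates) rather than asserting exact
  unbiasedness.

A small positive measurement bias (~0.1 deg) also enters every
peak-to-peak value through the max-minus-min statistic applied to noisy
traces; it shifts $I$ and $E$ equally, leaving the slope untouched and
the setpoint shifted by about +0.1 deg.

## Morphometry

`stack_volume()` implements the serial-section volume approximation:
per-slice label area (pixel count x squared pixel size) multiplied by
slice thickness (10 or 30 um in the standard protocols) and summed over
slices, with no overlap correction between adjacent slices — exactly
the published estimator. `dendrite_soma_ratio()` reports the
dendrite/soma volume ratio used to compare cerebellar maturity. On a
voxelised ellipsoid phantom sliced at 10 um the estimator lands within
10% of $\frac{4}{3}\pi abc$; it is exactly additive across substacks,
linear in thickness and quadratic in pixel size.

## Problem sizes and reproducibility

All simulations are seeded; identical seeds give bit-identical cohorts.
The recovery experiments in the test suite and in
`scripts/acceptance.R` use 20 replicates of the published cohort sizes
with full 30-min sessions at 30 fps (resampled to 200 Hz), about six
minutes of compute in total on one core; exploratory work can use
shorter `duration`s, which scale everything proportionally. Unit and
property tests run on 40 s-600 s sessions.

## What the synthetic tests do and do not show

The generator reproduces the *published summary structure* of the data:
pre-training amplitude distributions, a linear amplitude-change rule
with the published slope and setpoint, cohort-level residual scatter
matched to the published $R^2$, fast-phase contamination, timestamp
jitter and tracker noise. It does not model retinal or pretectal
processing, closed-loop visual feedback (the simulated eye does not
feed back onto its retinal slip), vergence or torsional components,
within-session fatigue, or any mechanistic account of where the
setpoint comes from. Passing recovery tests therefore demonstrate that
the *measurement pipeline is faithful and unbiased within the stated
tolerances* — they validate the analysis, not the biology.

## Worked example

```{r, eval = FALSE}
library(okrplast)

cohort <- simulate_group("old", seed = 1)
summaries <- analyze_cohort(cohort)
fit <- regress_change(summaries)
fit
glance(fit)
autoplot(fit)

# paired pre/post comparison within one paradigm, as in the original
with(subset(summaries, paradigm == 4),
     wilcoxon_signed_rank(entrained_deg, immediate_deg))

# population time course
plot_population_average(population_cycle_average(summaries), period_s = 20)
```
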