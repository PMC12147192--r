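---
title: "Projecting frontal-plane CoM transfer with a linear inverted pendulum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting frontal-plane CoM transfer with a linear inverted pendulum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comtransfer)
```

## The model

During each step of human walking the whole-body center of mass (CoM)
is transferred laterally towards the leading stance limb, reaches a
minimum mediolateral distance to the stance foot, and falls back. The
magnitude of that transfer — the minimum CoM-to-stance-foot distance —
is reduced and more variable towards the paretic side after stroke,
and is the central outcome this package computes.

`comtransfer` models the frontal-plane CoM as a linear inverted
pendulum (LIPM): a point mass at constant height $l$ whose
mediolateral position $x$ relative to the stance-foot pivot obeys
$\ddot x = \omega^2 x$ with eigenfrequency $\omega = \sqrt{g/l}$,
$g = 9.81\,$m/s$^2$. In the stance-foot frame the direction from pivot
to CoM is negative, so $x_0 < 0$ during a transfer and the approach
velocity $\dot x_0 > 0$. The passive trajectory is

$$x(t) = x_0\cosh(\omega t) + \frac{\dot x_0}{\omega}\sinh(\omega t).$$

Setting $\dot x(t^*) = 0$ gives
$\omega t^* = \operatorname{artanh}\!\big(\dot x_0/(\omega|x_0|)\big)$,
defined while the ratio $u = \dot x_0/(\omega |x_0|)$ stays below 1;
at $u \ge 1$ the pendulum would fall laterally over the pivot and no
minimum exists (`status = "fall_over_pivot"`). Substituting $t^*$
yields the *projected transfer magnitude*

$$M = x_0\cosh(\omega t^*) +
      \dot x_0 \tfrac{1}{\omega}\sinh(\omega t^*)
  = -\sqrt{x_0^2 - (\dot x_0/\omega)^2},$$

a negative number whose absolute value is the projected closest
approach. The two addends are the foot-placement (FP) related and
velocity related components, with coefficients $\cosh(\omega t^*)\ge 1$
and $\sinh(\omega t^*)/\omega \ge 0$. The right-hand closed form shows
that $M$ is a function of the conserved orbital energy
$\dot x^2 - \omega^2 x^2$ alone: along any passive stretch of the
trajectory every instant projects to the same minimum, and any change
in $M$ measures external work input. That identity is both the
scientific point (double-support changes in $M$ reflect trailing-limb
work) and the package's main internal consistency check.

Two conventions are worth stating. The inverse function here is the
inverse *hyperbolic* tangent: its domain $(-1, 1)$ is exactly the
validity condition above, and the closed form it produces matches
Runge–Kutta integration of the pendulum equation to $10^{-9}$ m (see
the test suite's oracle helpers). And when $\dot x_0 < 0$ (CoM already
receding) the minimum under passive dynamics lies at or before the
evaluation instant, so the projection returns the current position
with `status = "receding"`; $\dot x_0 = 0$ is the degenerate valid
case $t^* = 0$.

## The pipeline

Per trial, the package consumes precomputed CoM and foot-CoM
trajectories (kinematic rate, nominally 100 Hz) plus per-belt ground
reaction forces (kinetic rate, nominally 1000 Hz). Processing follows
the conventions of instrumented-treadmill gait analysis:

* **Filtering** — zero-phase (forward–backward) 4th-order Butterworth,
  6 Hz for kinematic and 15 Hz for kinetic channels. Zero-phase
  application avoids lag-shifting event times; the magnitude response
  is squared. Signals are extended by odd reflection before filtering
  to suppress edge transients.
* **Velocity** — central differences of the filtered CoM position at
  the kinematic rate; event-instant values by linear interpolation;
  for power computation the velocity is interpolated onto the kinetic
  timeline.
* **Events** — initial contact (IC) and contralateral foot off (CFO)
  from the vertical belt forces: threshold crossing (default 20 N)
  with 50 ms persistence on both sides of the crossing, crossing times
  interpolated between samples. Transfer completion is the minimum
  mediolateral CoM-to-stance-foot distance inside the single-support
  window, refined to sub-sample resolution by a parabolic fit; minima
  sitting on the window boundary are flagged and excluded.
* **Exclusions** — steps overlapping `handrail`/`crossover`/`toe_drag`
  annotations, automatic crossover detection (leading foot across the
  belt midline at IC), fall-over-pivot states, boundary minima,
  incomplete windows. Toe drag is not detectable from these channels
  and is honored via annotations only.

Per step the pipeline then computes foot placement and CoM velocity at
IC, projections $M_{IC}$ and $M_{CFO}$, the realised final magnitude,
the telescoping phase changes
$\Delta_{DS} = M_{CFO} - M_{IC}$ and
$\Delta_{ESS} = M_{final} - M_{CFO}$, and the trailing-limb
mechanical work: power is the product of the trailing belt's
mediolateral force and the CoM velocity, both mapped into the
leading-stance sign convention; work is the trapezoidal integral over
double support. Participant-level summaries follow: per-side means,
asymmetries (non-paretic minus paretic; positive = greater transfer
toward the non-paretic side), phase contributions (percent of the
final asymmetry established at IC, during double support, during early
single support — summing to 100% identically), the per-side mean
absolute error of the CFO prediction, the per-side Pearson correlation
between $M_{IC}$ and $\Delta_{DS}$ across steps, and per-side SDs of
$M_{IC}$ and $M_{final}$. Variability at CFO is deliberately not
emitted. Group-level inferential statistics (mixed models, ANOVA,
multiplicity corrections) are consumers of the emitted tidy tables,
not pipeline stages.

## The synthetic generator

No public dataset accompanies this kind of protocol, so the package
ships a generator whose trials exercise every pipeline stage with
exact ground truth. Within a step the stance-frame CoM follows LIPM
dynamics: passive in single support, and
$\ddot x = \omega^2 x + a\sin(\pi\tau/T_{DS})$ during double support —
a half-sine trailing-limb force per unit mass, smooth and zero at both
ends. Both regimes have closed-form solutions (the forced equation has
the particular solution $-a\sin(\Omega\tau)/(\omega^2+\Omega^2)$), and
the injected work is an exactly quadratic function of the amplitude
$a$, so the amplitude that meets a step's work target is obtained by
solving a quadratic, not by iteration. Trajectories, event times and
logged work are therefore exact to machine precision; the
Runge–Kutta integrator appears only as an *independent oracle* in the
test suite. Work injection is either a per-side target (with Gaussian
step-to-step variability `work_sd`) or a step-to-step controller that
moves the projection a fraction `compensation_gain` of the way to
`target_magnitude` — the latter produces the textbook $r = -1$
correlation between $M_{IC}$ and $\Delta_{DS}$ and collapses the
final-magnitude variability to the residual floor.

Three design points deserve explanation:

* **Step timing is emergent.** In a pure frontal-plane LIPM the step
  period is dictated by the dynamics: double-support duration plus the
  stationary time plus the passive fall-back to the next approach
  speed. The `step_period` configuration value is therefore nominal;
  with `ds_fraction` it fixes only the double-support duration
  (default $0.285 \times 0.7 = 0.2$ s), and the realised period
  (~0.55–0.7 s) emerges.
* **Lateral position control.** Independent per-side draws of foot
  placement, velocity and work make the mediolateral CoM position a
  random walk, which would carry the walker off the belt. Real
  treadmill walkers hold station; the generator does the same through
  two channels. The side split of the mean approach velocity is solved
  from the steady-state zero-net-drift condition (notably, with a
  trailing-limb work deficit this solution *requires* a faster
  approach velocity towards the paretic side — the same compensatory
  velocity asymmetry observed in hemiparetic gait). Residual wander is
  damped by weak per-step corrections: mainly through the approach
  velocity (`v_centring_gain`), because under passive dynamics a wider
  placement deepens the subsequent fall-back almost exactly and barely
  shifts the net displacement, leaving placement (`centring_gain`) a
  weak lever.
* **Default conditions emulate slow post-stroke treadmill gait**: CoM
  height 1.0 m, approach velocity ~0.15 m/s, foot placement 15 cm
  (non-paretic) versus 17 cm (paretic, a 2 cm widening), double
  support 0.2 s, trailing-limb work ~3.5 J on non-paretic transfers
  and 30% less on paretic transfers, 1 mm kinematic and 2 N kinetic
  noise, 100/1000 Hz sampling. The slow timing matters beyond realism:
  the 6 Hz kinematic cutoff is faithful for such gait, whereas a much
  faster synthetic cadence would push genuine signal past the cutoff.
  CoM height is held exactly constant (observed in-vivo variation
  during transfer is ~1% of body height, so the constant-height
  assumption is benign). Vertical load transfer is modeled as linear
  ramps — sufficient for threshold-based event detection, not claimed
  physiological; the stance-belt mediolateral force is tapered out
  shortly before the contralateral contact so the trailing-force
  channel the pipeline integrates is continuous.

What the generator does *not* emulate: anterior-posterior dynamics,
swing-leg dynamics and arm swing, angular-momentum (flywheel) effects,
soft-tissue artefact, marker occlusion, and the acceleration
*continuity* of real gait — the piecewise model switches pivots
instantaneously at IC, a kink real data does not share. Passing tests
therefore demonstrate the correctness of the computational chain under
the stated statistical structure, not clinical validity on real
recordings.

## Numerical choices and degenerate inputs

* Projection validity is classified before evaluation: `valid`
  ($0 \le u < 1$), `receding` ($\dot x_0 < 0$), `fall_over_pivot`
  ($u \ge 1$, including exactly 1: the asymptotic approach has no
  finite minimum). $x_0 = 0$ is a degenerate-state error.
* The completion search requires at least 3 kinematic samples in the
  single-support window (`incomplete` otherwise) and refines the
  discrete minimum with a parabolic vertex clamped to one sample.
* Work integration requires at least 3 kinetic samples in the
  double-support window; trapezoidal quadrature is exact for the
  constant-force, constant-velocity case and accurate to well under 1%
  for the half-sine profile at 1000 Hz.
* On exact (unfiltered, fine-rate) samples the metric layer conserves
  the projection along passive stretches to $10^{-5}$ m; through the
  full 100 Hz / 6 Hz-filter path the projection at *foot off* predicts
  the realised minimum to under 0.5 mm (the trajectory is smooth
  there), while the projection at *initial contact* carries a few mm
  of filter-induced distortion from the generator's pivot-switch kink.
  With 1 mm marker noise the foot-off prediction error is of the order
  of the noise (0.5–3 mm per-side MAE), which is the regime reported
  for marker-based motion capture.
* All magnitudes are kept signed (negative) internally; absolute
  values are for display only. A positive asymmetry means greater
  transfer toward the non-paretic side.

## Worked trade-off example

```{r tradeoff}
# with FP coefficient 1.05 and velocity coefficient 0.10 s, offsetting
# a 1 cm wider placement takes ~0.1 m/s of extra approach velocity --
# a 67% increase over a typical 0.15 m/s -- and placement carries
# about ten times the influence of velocity, putting its share of a
# 53.9% initial-contact contribution at 49%
velocity_offset_for_fp(0.01, 1.05, 0.10)
fp_share_of_final_asymmetry(53.9, 10)
```

## A small end-to-end run

```{r pipeline}
sim <- simulate_trial(synthetic_config(n_steps = 12, seed = 42))
metrics <- compute_step_metrics(sim$trial)
summary_row <- participant_summary(metrics, "demo")
round(1000 * c(asym_ic = summary_row$asym_ic,
               asym_cfo = summary_row$asym_cfo,
               asym_final = summary_row$asym_final), 1)  # mm
round(c(ic = summary_row$contrib_ic, ds = summary_row$contrib_ds,
        ess = summary_row$contrib_ess), 1)               # %
```

Problem sizes used throughout the package's own verification: trials
of 8–30 steps, cohorts of 12 participants, and 50-seed repetitions for
the recovery properties.

## Known limitations

The projection inherits every LIPM assumption: constant CoM height, a
point mass without angular momentum, a passive leading limb that only
redirects (never adds) energy. Trailing-limb work computed from the
mediolateral force alone understates three-dimensional limb work. The
generator's exclusion machinery (handrail, toe drag) is exercised via
annotations, not simulated physics. And the package deliberately stops
at tidy per-step and per-participant tables: inference across
participants belongs to downstream mixed-model tooling.
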