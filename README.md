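# comtransfer

Frontal-plane center-of-mass (CoM) transfer analysis for treadmill
gait, built for researchers studying mediolateral balance control in
hemiparetic (post-stroke) walking.

In every step the body CoM is transferred laterally towards the
leading stance limb; the transfer magnitude is the minimum
mediolateral CoM-to-stance-foot distance of the step. After stroke
this transfer is typically smaller and more variable towards the
paretic side. `comtransfer` implements a physics-based projection
that converts the instantaneous CoM state into the transfer magnitude
the step is heading for, and a complete pipeline that uses it to
locate *when* within the step the paretic/non-paretic asymmetry is
established.

## The core equation

Modelling the frontal-plane CoM as a linear inverted pendulum
(eigenfrequency ω = √(g/l), stance-foot frame with the medial
direction negative), the passive trajectory from state (x₀, ẋ₀) is
x(t) = x₀·cosh(ωt) + (ẋ₀/ω)·sinh(ωt). Its stationary point
ωt\* = artanh(ẋ₀/(ω|x₀|)) exists while ẋ₀/(ω|x₀|) < 1, and the
projected transfer magnitude is

    M = x₀·cosh(ωt*) + (ẋ₀/ω)·sinh(ωt*) = −√(x₀² − (ẋ₀/ω)²)

which splits into a foot-placement component (coefficient cosh(ωt\*))
and a CoM-velocity component (coefficient sinh(ωt\*)/ω). Because M is
a function of the conserved orbital energy ẋ² − ω²x², it stays
constant along passive motion and *changes only when external work is
injected* — which is what makes per-phase comparisons meaningful:
evaluated at initial contact (IC), at contralateral foot off (CFO)
and at transfer completion, the projection decomposes the final
asymmetry into contributions of foot placement at IC, trailing-limb
work during double support, and early single support.

## What the package provides

* `pendulum_state()`, `projected_transfer_magnitude()`,
  `closed_form_magnitude()` — the projection mathematics.
* `read_trial()` / `write_trial()`, `butterworth_lowpass()`,
  `differentiate()`, `preprocess_trial()` — trial bundles (TSV +
  JSON metadata), zero-phase 4th-order Butterworth filtering (6 Hz
  kinematic / 15 Hz kinetic), velocity derivation and stream
  alignment.
* `detect_contact_events()`, `segment_steps()`,
  `find_transfer_completion()` — force-threshold gait events and step
  segmentation with exclusion rules (annotations, crossover,
  fall-over-pivot, boundary minima).
* `compute_step_metrics()`, `trailing_limb_work()` — all per-step
  scalars including double-support trailing-limb work, power, force
  and velocity.
* `participant_summary()`, `analyze_cohort()` plus helper calculators
  (`velocity_offset_for_fp()`, `fp_share_of_final_asymmetry()`) —
  asymmetry evolution, phase contributions, prediction error,
  step-to-step control, variability.
* `synthetic_config()`, `simulate_trial()`, `simulate_cohort()` — a
  synthetic treadmill-trial generator with exact analytic ground
  truth (closed-form LIPM dynamics with half-sine trailing-limb force
  injection), so the whole pipeline is testable without motion
  capture hardware.

A thin command-line wrapper lives in `inst/cli/comtransfer.R`
(`simulate` and `analyze` subcommands).

## Worked example

```r
library(comtransfer)

# How much faster must the CoM approach to offset a 1 cm wider foot
# placement, with typical coefficients 1.05 (placement) and 0.10 s
# (velocity)?
velocity_offset_for_fp(0.01, 1.05, 0.10)
#> [1] 0.105        # ~0.1 m/s, a 67% increase over a 0.15 m/s mean

# Simulate one hemiparetic trial and summarise it
sim <- simulate_trial(synthetic_config(n_steps = 12, seed = 42))
metrics <- compute_step_metrics(sim$trial)
s <- participant_summary(metrics, "demo")
round(1000 * c(s$asym_ic, s$asym_cfo, s$asym_final), 1)
#> [1] 26.5 44.9 45.4    # mm: asymmetry grows during double support
round(c(s$contrib_ic, s$contrib_ds, s$contrib_ess), 1)
#> [1] 58.5 40.5  1.0    # % of the final asymmetry per phase
round(1000 * c(s$mae_p, s$mae_np), 2)
#> [1] 0.87 0.99         # mm: foot-off projection vs realised minimum
```

The asymmetry row reads: a positive value means greater transfer
towards the non-paretic side; about half of the final asymmetry is in
place at initial contact (wider paretic foot placement) and most of
the rest accrues during double support (reduced trailing-limb work on
paretic transfers). The sub-millimetre MAE confirms that from foot
off onward the CoM behaves as a passive pendulum.

(Exact numbers above are from this seed; your platform should
reproduce them bit for bit.)

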