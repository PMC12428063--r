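---
title: "Modelling temperature-controlled nanosecond-pulse ablation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling temperature-controlled nanosecond-pulse ablation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`nsablate` models a single internally cooled needle electrode delivering
bipolar nanosecond pulses into liver tissue against a dispersive grounding
pad, under closed-loop temperature control. This vignette is the package's
account of the science: the model and its assumptions, the parameters and
where their defaults come from, the numerical choices, what the synthetic
cohort does and does not emulate, and the known limitations — in
particular of the lethal-threshold calibration.

## The physical model

**Geometry.** The problem is rotationally symmetric about the needle axis
and is posed on the (r, z) half-plane: a 45 cm long, 45 cm radius tissue
cylinder; a grounded 7.6 cm radius disc (the pad) on the bottom face; a
needle of 0.08255 cm outer radius sheathed in 0.02032 cm of insulation
except for an exposed distal segment of 0.5–2.0 cm; a 0.0228 cm internal
coolant channel. The insertion depth (tip 10 cm below the top surface) is
not part of the published device description; the default was chosen so
that every lethal iso-contour stays at least 5 cm from all outer
boundaries, making the solution insensitive to it, and it is configurable.
The trocar tip is simplified to a flat disc face: nothing in the modelled
geometry description specifies the tip shape, a flat face is the plain
reading of a "tube", and the calibration contour lies 1–2 cm away where
tip details are negligible (the tip face does carry the field maximum,
which matters for the *thermal* hot spot — see below). The coolant channel
itself is not meshed; the entire coolant loop is reduced to a boundary
condition on the applicator wall, so the mesh carries five boundary tags
(`ELECTRODE`, `INSULATION`, `PAD`, `FARFIELD`, `AXIS`).

**Electrostatics.** Current continuity `div(sigma grad V) = 0` with
`V = 6000 V` on the exposed electrode, `V = 0` on the pad, and zero normal
current elsewhere — the quasi-static (DC) treatment of the 1000 ns pulses.
Tissue permittivity, dispersion and electrode double-layer effects are out
of scope. Baseline conductivity is 0.4 S/m (liver at 1 MHz, the frequency
scale matching a 1000 ns pulse). Conductivity may rise linearly with
temperature, `sigma(T) = sigma0 (1 + alpha (T − T_ref))`; the coefficient
is not part of the published description, so the package defaults to the
common soft-tissue literature value `alpha = 0.015 /degC`, flagged as the
dominant uncertainty for coupled runs.

**Calibration field.** The lethal threshold is matched against the
*baseline* (uniform-sigma) field by default. Under uniform sigma the field
distribution is a purely geometric quantity — independent of the sigma
magnitude and of everything thermal — which makes the calibration exactly
reproducible. A coupled option (`solve_potential(..., temperature = )` or
`simulate_treatment(coupled_sigma = TRUE)`) re-evaluates sigma from a
temperature field instead. See *Limitations* for why this choice matters.

**Thermal model.** Transient conduction
`rho Cp dT/dt − div(k grad T) = Qe` with the duty-cycle-scaled Joule
source `Qe = R(t) 1e-6 (J · E)`, where `R(t)` (microseconds of pulse
on-time per second) is the controller's actuated variable. There is no
blood-perfusion sink: the governing equation of the source model contains
none, and a Pennes-type term is deliberately not added so that the two
models stay comparable. `rho = 1079 kg/m^3`, `Cp = 3540 J/(kg K)`,
`k = 0.52 W/(m K)` are liver values from the same public tissue-property
database that supplies the conductivity; they are implementer defaults,
not published model constants.

**Boundary conditions and the coolant.** Far boundaries are held at the
baseline tissue temperature, 33 degC by default with 22 degC coolant. The
33/22 pairing reconciles two observations that a single number cannot: the
sensor on the cooled applicator reads approximately 25 degC before
delivery, while porcine core temperature is substantially higher. Both
values are configurable. The coolant loop (10 mL/min water) is a
convective wall condition: on the bare cooled electrode the film
coefficient defaults to 5000 W/m^2 K — the laminar forced-convection
estimate for that flow in a 0.0228 cm radius channel (v ≈ 1 m/s, Nu ≈
3.7) — and on the insulated shaft the polyimide layer's conduction
resistance is added in series (effective ~550 W/m^2 K). The distal 0.5 cm
of the electrode carries no internal cooling, but the steel tube is not
adiabatic: axial conduction to the cooled section is represented by a
reduced effective coefficient (default 1000 W/m^2 K) on the distal wall
and tip face. A `fixed` coolant model (wall clamped at the coolant
temperature) is available; it shortens simulated treatments but produces
unphysically hot tips, and is not the default.

## The controller

The real device adjusts the delay between successive bipolar waveforms
under a proprietary control law; only its observable behaviour is
documented (ramp to the setpoint within tens of seconds, a stable 45 degC
plateau, longer treatments for shorter electrodes). The package therefore
implements the simplest law reproducing that behaviour — a proportional
band throttle,

```
rate(T) = max_rate * clamp((setpoint − T) / band, floor, 1)
```

with `max_rate = 100 us/s`, `band = 2 degC`, `floor = 0.02`, updated every
0.25 s, plus a first-order smoothing of the commanded rate (time constant
3 s). The smoothing stands in for the generator's finite slew and damps
the loop: the probe sits in the steepest part of the field, where an
unfiltered proportional law at this step size chatters between its limits.
The floor guarantees the dose always completes; the dose ledger advances
by `rate * dt * 1e-6` seconds per step and the final step is shortened so
the delivered dose equals the prescription exactly, to the nanosecond.

**The probe.** The sensor sits at the insulation–electrode junction. In
the simplified geometry that point is a reentrant corner where the field —
and hence the Joule source — is singular, so the corner-node temperature
does not converge under mesh refinement. The probe therefore samples
0.5 mm into the tissue at the junction plane (`probe_location()`),
emulating the finite-size sensor; the offset is an argument.

## Numerics

* **Meshing.** Graded tensor-product grid whose lines pass through every
  material feature, so no element crosses a material boundary and tags are
  exact; 100 um cap within 1 mm of the applicator, geometric growth
  (ratio 1.35) to a 5.14 mm far cap. Degenerate inputs are rejected by
  named constraint.
* **Adaptive refinement.** Elements with |E| > 250 V/cm are bisected
  (longest-edge marking with red–green closure keeps the mesh conforming),
  two rounds with a re-solve in between, approximating the commercial
  adaptive scheme of the source model. Production meshes run to ~60k–125k
  elements; the element-count bracket of the original model (269k–842k) is
  solver-specific and treated only as an order-of-magnitude sanity check.
  Total current changes by < 0.3% across the two rounds.
* **FEM.** P1 triangles; all cylindrical integrals carry the exact linear
  variation of r over an element; lumped mass for the transient solver;
  implicit Euler (unconditionally stable), operator factorised once per
  (mesh, dt) so a treatment step is one triangular solve. Electrode
  current is extracted from the stiffness residual at Dirichlet nodes,
  which makes electrode and pad currents balance to machine precision.
* **Iso-volumes.** `volume_above_field()` clips the linear nodal
  interpolant inside elements crossing the contour and revolves the
  clipped polygons exactly (2*pi*r-weighted first moments); an
  element-selection mode reproduces the coarser estimate. Against the
  concentric-sphere closed form the solver is within ~0.1% on current and
  ~0.2% on iso-volume at the test resolution.
* **Threshold matching.** Monotone linear interpolation on the 10 V/cm
  grid by default (`mode = "grid"` reproduces the raw grid resolution).
  Volumes outside the curve's range are clamped to the nearest endpoint
  and flagged. Round-tripping a volume through the curve recovers the
  field level to < 10 V/cm.
* **Sphericity.** Reported as axial length over maximal transverse width
  (2 x max radial extent) of the iso-region; of the two perpendicular
  width measurements a CT analysis would give, the model's axisymmetry
  provides only one.

## The synthetic cohort

Only group-level summaries of the in vivo measurements are published
(per exposure: replicate count, treatment time and ablation volume as
mean ± SD). `generate_cohort()` draws per-replicate volumes and times from
normal distributions with exactly those moments, truncated at zero —
a plain normal puts non-negligible mass below zero for the widest group
(7.95 ± 3.74 cm^3), and a negative ablation volume is meaningless. The
truncation's induced mean shift is what the tests measure it to be:
negligible for the tight groups and a small upward shift for the wide
ones. Volumes and times are drawn independently (no joint distribution is
published; a correlation would be speculation). The generator does not
emulate imaging or segmentation error explicitly (absorbed in the SD) nor
the study's exclusion rule for lesions crossing lobe boundaries, which
implies an informative censoring that summaries cannot reconstruct.
Passing cohort-based tests therefore demonstrates that the calibration and
statistics stages are correct *given* the published group structure — not
that the generator reproduces every feature of real measurement noise.

## Problem sizes used by the tests

The unit tests run on coarsened meshes (0.5–1.5 mm near sizes, a few
thousand elements) chosen to exercise every code path quickly; the
acceptance-level calibration runs use the full production mesh settings;
the treatment simulations in the end-to-end checks use 0.6 mm near sizes,
the scale at which the controller behaviour and iso-volume orderings are
mesh-stable.

## Limitations

* **Absolute lethal thresholds.** The calibration reproduces the
  *structure* of the published thresholds well — the ordering across
  exposures (2.0 cm highest, 0.5 cm lowest) and the threshold ratios
  between geometries — but the absolute values computed from the baseline
  field run some 15–30% above the published means (the acceptance script
  computes them; the 1.0 cm geometry lands closest). The package's
  electrostatics is verified against closed forms and an independent
  finite-volume solver to sub-percent accuracy, and the baseline field is
  deliberately geometry-only, so this offset reflects a modelling
  difference rather than a numerical one: the source model solved a
  time-dependent problem with temperature-dependent conductivity, and its
  own discussion flags the computed field distribution around the
  electrode as a potential confounder of the threshold spread. A
  sigma(T)-coupled solve in this package *raises* the computed iso-volumes
  (the warm far field dominates over the cooled sheath), so no
  physically-motivated setting of the coupling reproduces the published
  absolute values; they should be treated as specific to the original
  model's thermal state. Users calibrating against their own measured
  volumes are unaffected: the matching machinery is exact for whichever
  field it is given.
* **Absolute treatment durations.** Simulated durations preserve the
  published ordering (shorter electrodes treat longer) and the 45 ± 1 degC
  plateau, but run several times longer than the observed times. At the
  probe's thermal equilibrium the wall-condition coolant model removes
  less power than the real internally cooled device (and the full
  conjugate CFD of the original model); matching observed rates would
  require clamping the wall to the coolant temperature, which destroys the
  fidelity of the simulated temperature field near the tip. The package
  prioritises the thermal field.
* **Desiccation and nonlinear conductivity** near the electrode are not
  modelled (nor were they in the source model, which names them as a
  candidate explanation for the threshold variability).
* **No thermal-damage integrals** (Arrhenius / CEM43): out of scope; the
  45/55/65 degC iso-volumes are reported instead.
* The 2-D axisymmetric idealisation cannot represent bent needles, lobe
  boundaries, or large vessels — all present in vivo.
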