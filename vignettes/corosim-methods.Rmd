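---
title: "corosim: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{corosim: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Overview

`corosim` simulates the left heart and systemic circulation coupled in a
closed loop with two nonlinear coronary arterial networks — the left
anterior descending (LAD) and left circumflex (LCX) territories — under
time-varying intramyocardial pressure (IMP) loading.  Its purpose is to
study how mechanical dyssynchrony (delayed activation of the LCX territory,
as in left bundle branch block or ventricular pacing) redistributes
regional coronary flow, and how flow-dependent regional contractility
(perfusion–contraction matching) feeds those changes back onto global
hemodynamics.

The model state is the four systemic storage volumes (left atrium, left
ventricle, arterial and venous compartments) plus one lumen volume per
coronary vessel (two 400-vessel trees by default, so ~804 ordinary
differential equations).  The right-hand side is implemented in C and
integrated with `deSolve`'s sparse stiff solver (`lsodes`).

## Chambers

Each chamber follows a time-varying elastance law: the pressure is the
activation-weighted combination of a linear end-systolic pressure–volume
relationship `Pes(V) = Ees (V - V0)` and an exponential end-diastolic
relationship `Ped(V) = A (exp(B (V - V0)) - 1)`.  The activation `e(t)`
is a raised half-sine up to 1.5 Tmax followed by exponential relaxation
with time constant `tau`; it is evaluated modulo the cardiac period so
delayed clocks are well defined in periodic steady state.  `V0` may be
negative for the ventricle: the linear extrapolation of the end-systolic
relationship crosses zero below the physiological volume range, which is
also required here for the stroke volume to carry the large calibrated
coronary flows.

The LV is split into an LAD-territory compartment (volume fraction `F`,
default 0.5) and an LCX-territory compartment that share the cavity
pressure; dyssynchrony delays the LCX activation clock by
`dt = T * SDI`.  Three cavity-pressure laws are implemented
(`corosim_model(lv_law = ...)`):

* `"shared"` (default): the closed form of the equal-pressure compartment
  system when the end-diastolic pressure is evaluated at the total volume.
  It reduces exactly to the single-chamber law for equal elastances and
  zero delay.  A numerical floor (1e-9 mmHg/ml) on the combined elastance
  weight returns the EDPVR pressure in deep diastole, where the closed
  form becomes 0/0.  A structural consequence of this law is that a
  relaxed compartment is infinitely compliant, so under dyssynchrony the
  cavity pressure rise waits for the late territory: the pressure, and
  with it the arterial pressure, shifts right by essentially the full
  activation delay.
* `"compartment"`: the exact partition system with each compartment's
  EDPVR evaluated at its own scaled volume (Newton solve per evaluation).
  A relaxed territory then retains its passive diastolic stiffness, the
  early territory raises pressure partially on time, and end-diastolic
  volume becomes much less sensitive to the delay.  Kept as a documented
  alternative and as the cross-check used by the test-suite (the two
  routes agree identically in the synchronous case).
* `"mixture"`: fixed volume split with the arithmetic-mean activation.
  Provided for completeness; it raises mean ventricular pressure under
  dyssynchrony and is not used by the packaged experiments.

The default is `"shared"`, which is the only law that reproduces the
dyssynchrony phenotype of the packaged experiments (larger end-diastolic
volume through delayed end-diastole with near-neutral mean arterial
pressure).

## Left-atrial timing

The atrial activation uses the same functional form with its own `Tmax`
(0.125 s) and is phase-advanced by `la_offset`.  The default
(`la_offset = 0.105` s, i.e. the atrial kick peaking just after
ventricular activation onset, with a slow atrial relaxation
`tau_LA = 0.08` s) was chosen, together with the mitral resistance default
(0.08 mmHg s/ml), so that in the synchronous state the ventricular
pressure rise truncates the atrial kick.  Delayed contraction then
releases the truncated kick volume, which is the mechanism by which
dyssynchrony enlarges the end-diastolic volume here.  With the kick
completed before activation onset (e.g. `la_offset = 1.5 * Tmax_LA`),
filling equilibrates early and dyssynchrony leaves the end-diastolic
volume unchanged; this alternative timing is a single config entry away.

## Systemic loop

Four volume ODEs close the loop; valves are ideal resistive diodes (no
regurgitation), peripheral and venous paths are linear resistances, and
the arterial/venous compartments are linear compliances.  The arterial
compartment loses the two coronary *inlet* flows and the venous
compartment gains the two *terminal outlet* flows, so total blood volume
including coronary lumen storage is conserved exactly; the networks store
the difference transiently.  There is no pulmonary compartment: venous
return feeds the atrium directly.

## Coronary trees

Each territory is an order-structured tree of nonlinear three-element
Windkessel vessels: half resistances `R1 = R2 = 64 mu L / (pi D^4)` and a
nonlinear capacitance defined as the derivative of lumen volume with
respect to transvascular pressure.  The diameter is a sigmoidal (arctan)
function of transvascular pressure with per-vessel constants `Ap`, `Bp`
(asymptotic radii), `phi_p` (pressure at mean radius) and `Cp`
(bandwidth).  Mid-node pressure minus the territory IMP is the
transvascular pressure.

Rather than integrating mid-node pressures with a product-rule capacitance
term, each vessel's lumen volume is the state variable; the mid pressure
is recovered by inverting the diameter law and junction pressures are
eliminated by a local Kirchhoff balance.  This makes volume bookkeeping
exact (inlet minus outlet flow equals the total lumen-volume rate
identically) and keeps the formulation non-stiff enough for `lsodes` with
rtol 1e-6 / atol 1e-8.

The generator builds trees with exactly the requested junction census
(default 195 bifurcations and 3 trifurcations, hence 400 vessels; the
structural identity forces 202 leaves).  Diameter-defined orders 0–6 are
assigned by rescaling the Strahler order so the root is order 6 and leaves
order 0.  The per-order diameter/length table is a *synthetic*
lumped-equivalent morphometry: the source reconstruction behind the
packaged experiments is not available, so the defaults were chosen once so
that the default tree's aggregate resistance supports the packaged
per-animal flow targets (which are large — the printed cycle-total
coronary flows are of the same order as the stroke volume) at
physiological perfusion pressures, with interior proximal-resistance
optima for all three animals.  Every quantity is user-overridable through
`morphometry_spec()`, and the solver accepts arbitrary tree files
(tab-delimited, one vessel per row).

Terminal vessels all drain through their own outlet half-resistance
directly to the venous pressure; inlet and outlet boundary pressures are
the systemic arterial and venous pressures.

## Intramyocardial pressure

Per territory, `IMP = alpha P_LV + beta Ees e + gamma (1 - SSR)` with
defaults alpha 0.8, beta 5 (ml), gamma 20 (mmHg): a cavity-induced
extracellular component (CEP), a time-varying-elasticity component (VE) on
the territory's activation clock, and a shortening-induced component (SIP)
through the stretch ratio `SSR = V_LV / EDV` (previous completed cycle's
EDV during integration; exact at periodicity).  IMP is homogeneous within
a territory.  `ve_cross = TRUE` switches the VE clocks between territories
(both readings of the component pairing are defensible from the source
description; the direct pairing is the default because it yields the
reported direction of the LCX flow change under dyssynchrony).  The
additional delay `dt_bar` shifts both territories' IMP activation clocks
relative to the cavity pressure.

## Scenarios, periodicity and the ischemia feedback

`run_to_periodic()` integrates cycle by cycle until the relative change of
EDV, peak LV pressure and both cycle-total coronary flows between
consecutive cycles falls below 1e-3 (cap 50 cycles).  Scenarios: `con`
(synchronous, equal elastances), `md` (LCX delay from the SDI), `md_is`
(additionally, each territory's maximal elastance is updated each cycle
from its previous cycle's cycle-total flow through the piecewise-linear
perfusion–contraction law, under-relaxed by 0.5; convergence additionally
requires the elastance update to fall below 1e-3 mmHg/ml).  The
contractility law is the plateau `Ees_n` at or above the transitional flow
`Qn` and the line of slope `k` through `(Qn, Ees_n)` below it, clamped at
zero; for the reference slope `k = Ees_n / Qn` this is the line through
the origin.  Slope multipliers steepen the line about the transition
point, which is what makes the tenfold-slope experiment meaningful.

Output is sampled at 1 ms, which resolves the dP/dt extrema at the default
0.6 s period; cycle means drop the final sample (it aliases phase zero).

## Calibration

The packaged measurement table holds the four scalar targets per animal
(cycle-total LAD and LCX flows, EDV, peak LV pressure).  `calibrate()`
replaces manual tuning with bounded Levenberg–Marquardt least squares of
the relative errors over an effective free set with near-diagonal
leverage: log proximal coronary resistances (flows), log peripheral
resistance (afterload / peak pressure), and a venous resting-volume offset
(preload / EDV; implemented as a parameter rather than an initial-state
change so warm-started evaluations remain volume-consistent).  The
finite-difference step of the optimizer (`epsfcn = 1e-4`, i.e. ~1%
parameter perturbations) must dominate the periodicity-criterion noise;
a second polishing pass with a finer step runs when the first stage leaves
more than 0.2% residual.  Tree constants and IMP weights are never
touched.  On the packaged targets all three animals fit to well below 0.1%
on all four targets in roughly one minute each (warm-started runs cost a
few cycles).

## Problem sizes and runtimes

The packaged study (`run_study()`) calibrates three animals and runs, per
animal, dyssynchrony at SDI 5/10/15%, the IMP-delay variant (SDI 10% with
`dt_bar = 0.07` s) and the two feedback scenarios, all with two 400-vessel
networks; it completes in about three minutes on one CPU.  The unit tests
use reduced trees (tens of vessels) except where the study scale is the
point.

## What the synthetic data do and do not show

The generator emulates the *structure* of the study conditions: the
junction census and order hierarchy of the coronary trees, per-order
morphometry statistics, and the fixed chamber/IMP constants.  It does not
reproduce the original animals' vasculature or the unpublished per-animal
systemic parameters; calibrated parameters here are functional
equivalents, not reproductions.  Passing tests therefore demonstrate the
behaviour of this model under these conditions, not agreement with any
particular animal's anatomy.

## Known limitations

* With the default (shared) pressure law, dyssynchrony shifts the cavity,
  arterial and IMP waveforms nearly together.  Cycle-total coronary flow
  in this Windkessel formulation is remarkably insensitive to the *phase*
  of the IMP relative to the perfusion pressure: compression of a vessel
  simultaneously raises its outlet driving pressure (the intramyocardial
  pump), and the two effects cancel to first order in the cycle integral.
  Across every vessel-compliance regime we explored (hard or soft
  collapse, distally or proximally dominated resistance, either VE
  pairing, all three pressure laws), a 0.07 s IMP shift moves cycle-total
  flows by only ~1–3%.  Consequently the simulated dyssynchrony flow
  redistributions have the reported directions (LAD up at moderate SDI,
  LCX down, EDV up) but magnitudes of a few percent rather than tens of
  percent; the corresponding acceptance checks are left failing rather
  than tuned.
* No coronary autoregulation (myogenic, metabolic or shear): flow is
  driven purely by perfusion pressure and IMP through passive vessels.
* No right ventricle or pulmonary circulation; no transmural IMP
  gradients; no valvular regurgitation; no wave propagation (0D network).
* The elastance LV ignores length-dependent activation and tissue
  anisotropy.

## Reproducing the packaged results

`scripts/acceptance.R --seed 1 --out results/acceptance.json` recomputes
the headline quantities (calibration errors, dyssynchrony flow changes,
IMP component fractions, feedback effects) from scratch; the test suite
asserts them with tolerances in `tests/testthat/test-acceptance.R`.
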