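---
title: "The sarcosim half-sarcomere model: mechanics, kinetics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The sarcosim half-sarcomere model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model in one paragraph

`sarcosim` simulates one half of a sarcomere — from the Z-line to the M-line —
as a one-dimensional chain of nodes connected by Hookean springs, driven by a
three-state actomyosin cross-bridge cycle. Thin-filament nodes are discrete
actin binding sites; thick-filament nodes are the bases of myosin heads. Each
head is either detached with hydrolysis products still bound (state 1,
M.ADP.Pi), attached pre-power-stroke (state 2, A.M.ADP.Pi), or attached
post-power-stroke (state 3, A.M). The innovation the model exists to express
is in the free-energy bookkeeping: ATP binding and the release of ADP and
inorganic phosphate occur at *different* transitions, so the ATP-driven
detachment rate depends only on `[ATP]` while the reverse power stroke
depends only on the product `[ADP][Pi]`. Contractile force, duty ratio,
ATP consumption, and rigor behaviour then respond to the two concentrations
independently, not merely to their ratio.

## Geometry

The Z-line is fixed at `x = 0`. Actin nodes sit at `a0 * i` (`a0` = 12.3 nm);
myosin nodes are spaced `m0` = 14.3 nm apart, with the M-line one spacing
beyond the last head and an external anchor a rest length `x_f0` = 100 nm
beyond that. Titin is a spring from the Z-line to the myosin node farthest
from the M-line. The whole system has `n_actin + n_myosin + 2` nodes (the
anchor is a fixed boundary, not a node).

Real sarcomeres are three-dimensional helical lattices; in one dimension the
only available source of cross-bridge disorder is the spacing mismatch
`a0 != m0`, which scatters the heads' offsets from their nearest binding
sites. The default registration places the first head exactly one
cross-bridge rest length `b0` = 10 nm beyond the first actin node (zero
distortion for that pair); `overlap_shift` translates the thick filament to
explore other registrations. The registration is a genuine modelling
freedom: quantities that depend on the *distribution* of binding strains
(multi-myosin mean force, the effective crowding of heads) inherit it, and
we make no attempt to tune it.

The reference systems are the minimal one-myosin lattice (`n_actin = 2`,
`n_myosin = 1`) and the 16-myosin, 24-actin half-sarcomere.

## Mechanics

All springs are linear. For a given cross-bridge configuration the
equilibrium is the solution of one linear system `K p = v`: one force-balance
row per free node, `K` symmetric with each diagonal entry equal to the sum of
stiffnesses incident on that node, and rest lengths plus fixed-boundary terms
in `v`. Systems are at most a few dozen unknowns, so a direct dense solve is
used (relative residual required below 1e-8). Mechanical relaxation is taken
to be instantaneous relative to chemistry: positions are re-solved after
every step that contains a chemical transition, and never integrated
dynamically.

A bound cross-bridge is a spring of stiffness `k_xb` = 3 pN/nm with rest
length `b0` in state 2 and `b0 - d_ps` in state 3 (`d_ps` = 7 nm is the
unloaded power-stroke distance). Contraction pulls the M-line toward the
Z-line and stretches the external spring; that stretch times `k_f` is the
recorded (positive) contractile force.

**Titin is slack in compression.** Contraction *shortens* the Z-line-to-thick-
filament distance, so a bidirectional Hookean titin at `k_t` = 10 pN/nm
would push back with tens of pN and cap the achievable sliding at well under
2 nm — incompatible with the ~1 nm residual cross-bridge extension and ~3 pN
holding force the one-myosin system is built to reproduce. Titin therefore
bears force only when stretched beyond its rest length (the solver checks the
engaged branch and re-solves on the slack branch when titin is compressed),
which is also the physically standard treatment of a tether that buckles
rather than supports compression. Titin still serves its structural role of
limiting extension.

**The external stiffness `k_f`.** The substrate stiffness has no canonical
value; it is what the sarcomere contracts against. We fix it once, in closed
form, from the one-myosin anchor observables: with near-rigid filaments a
post-stroke cross-bridge relaxes to extension
`e = d_ps * k_net / (k_xb + k_net)` where `k_net` is the series stiffness of
everything behind it (dominated by `k_f`), and holds force `k_xb * e`.
Requiring `e = 1` nm — equivalently a 3 pN one-myosin holding force and an
effective sliding distance of `d_ps - 1` = 6 nm — gives `k_f = 0.5` pN/nm.
This is a calibration of a genuinely free constant against the model's own
one-myosin anchor point, done before any multi-myosin simulation and not
revisited.

## Kinetics

Energies are accepted in `kBT` units (`kBT` = 4.14 pN nm) and converted once.
With strain `s = x_m - x_a - b0`:

* `G1 = 0` (reference),
* `G2 = dG_bind + k_xb s^2 / 2`,
* `G3 = dG_bind + dG_stroke - dG_DPi,rel + k_xb (s + d_ps)^2 / 2 + kBT ln([ADP][Pi])`,
* `G1' = -dG_hyd - kBT ln([ATP] / ([ADP][Pi]))`,

with `dG_bind = -4 kBT`, `dG_stroke = -4.5 kBT`, `dG_DPi,rel = -14 kBT`,
`dG_hyd = 13 kBT` (the standard hydrolysis free energy at the fixed 1 M
reference concentrations), concentrations in molar. `G1'` is the baseline of
the next cycle: at standard concentrations (`[ATP]` 5 mM, `[ADP]` 0.03 mM,
`[Pi]` 3 mM) the full drop per hydrolysis is `|G1'| ~ 23.9 kBT`, the
physiological value — this is why the standard part of the hydrolysis energy
is identified with the 13 kBT constant while the concentration terms are
written out explicitly in the rates.

The six rates follow from prefactors plus detailed balance:

* `k12 = k_bind exp(-beta k_xb s^2 / 4)` — the attachment transition state
  sits halfway up the elastic well, so the forward rate carries one quarter
  of the elastic penalty and detachment `k21 = k12 / K12` picks up the rest;
* `k23 = k23_cap` = 30 1/s — the power stroke is flat-rated; its reverse
  `k32 = k23 / K23` carries the `[ADP][Pi]` dependence and the elastic cost
  of re-cocking;
* `k13 = k_ATP0` = 0.01 1/s — reverse hydrolysis; the forward, ATP-driven
  detachment `k31 = K31 k13` carries the `[ATP]` dependence.

Around the cycle the elastic terms cancel exactly and the product of
forward-over-backward rates equals
`[ATP]/([ADP][Pi]) * exp(dG_hyd / kBT)` at every strain — the thermodynamic
consistency identity that the test suite verifies to 1e-10.

Note an immediate structural consequence: the *net* cycle flux through any
head is bounded by `k23 = 30` per second (the stroke is the bottleneck), so
no parameterisation of this cycle can consume more than ~30 ATP/s per head.

## Stochastic scheme

Chemistry advances with a fixed-step kinetic Monte Carlo: per step of
`dt = 1e-5` s each head (visited in a fresh random permutation, so
binding-site contention carries no index bias) draws a single uniform number
against the probabilities `1 - exp(-k dt)` of the at-most-two transitions
available to it, taking at most one transition per step. A detached head
targets the unoccupied binding site minimising `|s|` (ties break toward the
Z-line; attempts beyond 20 nm are suppressed purely as a numerical guard —
the attachment Boltzmann factor has long since extinguished such rates). A
site freed earlier in a step is immediately re-eligible; a site claimed
earlier in a step is not.

The step size is chosen so the fastest *routinely visited* rate — ATP-driven
detachment at the relaxed post-stroke strain, ~8e3 1/s at standard
concentrations — keeps `k dt` below 0.1. Rates at strains the dynamics never
dwell in (e.g. the reverse stroke at zero strain, ~2e6 1/s) would demand
absurd steps, but mechanics re-equilibrates within the same step in which
such configurations arise; a startup check therefore validates `dt` against
the rest-geometry binding strains and the relaxed detachment strain, warns
(rather than errors) when violated, and per-step probabilities are capped at
0.95 with a logged count. Extreme grid corners (`[ATP]` = 0.1 M) lean on the
cap; the resulting dwell-time discretisation bias is a few percent there and
negligible at physiological conditions. Halving `dt` moves the one-myosin
duty ratio by less than a replicate standard error (tested).

Every run starts with all heads detached and the lattice at rest; the
plateau rule below removes the initialisation transient from rate estimates.
Runs are bit-reproducible from the seed; sweep replicate seeds derive
deterministically from one master seed.

## Observables

* **Duty ratio** — exact per-head fraction of simulated time in state 3,
  averaged over heads (accumulated per step, not from thinned samples).
* **Force** — external-spring force at recorded samples (default every
  1 ms); the peak is reported both raw and smoothed over a 12 ms window.
* **Plateau ATP rate** — 3-to-1 events in a 50 ms sliding window; the
  plateau is the mean windowed rate from the first time it exceeds 98% of
  its maximum. Reverse (1-to-3) events are logged and subtracted in the net
  turnover count.
* **Effective sliding distance (ESD)** — mean of `-s` over all state-3
  head-steps; under load it falls short of `d_ps`.
* **Energy ledger** — `energy_audit()` reports the elastic energy stored in
  all springs against two inputs: net hydrolysis events times `|G1'|`, and a
  full chemical ledger that also credits the binding and stroke drops of
  heads currently mid-cycle. The hydrolysis-only ledger necessarily
  undercounts early in a run (each head starts as M.ADP.Pi, so elastic
  energy funded by `|dG_bind|` = 4 kBT per binding appears before any
  turnover completes); the full ledger is the thermodynamically meaningful
  bound and is what the property tests assert on configurations where
  thermal harvesting cannot confound it.

## The analytic one-myosin surrogate

For one head the master equation of the cycle has the closed-form stationary
weights given in `steady_state()`; the test suite checks them to 1e-10
against a brute-force null-space solution for a thousand random rate sets.
The strain dependence is collapsed through the ESD: attachment happens near
zero distortion, so `k12`/`k21` are evaluated at `s = 0`, while the
post-stroke rates `k32`/`k31` are evaluated at `s = -esd`. (Evaluating the
attachment pair at `-esd` too would describe a head that binds at the
post-stroke distortion; it suppresses the analytic duty ratio by three
orders of magnitude and cannot reproduce any simulated grid.) Average force
is `duty_ratio` times a reference peak force, 3 pN by default — itself a
simulation output, kept configurable.

`fit_esd()` inverts the surrogate: given a simulated duty-ratio grid over
`([ATP], [ADP][Pi])` it finds the single ESD minimising the mean squared
*log* duty-ratio difference (duty ratios span orders of magnitude across a
grid; a linear objective would fit only the rigor corner). Cells with zero
observed state-3 time are excluded; a constant reference is rejected as
unidentifiable. The one-myosin grid is expected to fit near 6 nm — the
series-compliance value built into `k_f` — while the crowded 16-myosin grid
fits a smaller ESD (~3-4 nm): internal bracing by neighbouring bound heads
keeps more elastic energy inside the sarcomere and leaves post-stroke heads
less relaxed.

## What the synthetic conditions emulate — and what they do not

The default grids (log-spaced, `[ATP]` from 1e-7 to 1e-1 M, `[ADP][Pi]` from
1e-12 to 1e-4 M^2) bracket standard physiological conditions (5 mM,
9e-8 M^2), the reported rigor-onset region (`[ATP]` ~ 0.5 mM and below), and
fatigue-like thousand-fold elevations of `[ADP][Pi]`. Passing tests on these
conditions show that the *kinetic schema* behaves correctly — independence of
the two concentration channels, rigor ratcheting at low `[ATP]`, the ESD
surrogate's validity. They do not show fidelity to any particular muscle:
the lattice is one-dimensional with a single thin filament per thick
filament, calcium activation is complete and permanent, there is no
super-relaxed myosin state, no compliant realignment of helical repeats, no
prescribed-velocity or isotonic protocols, and multi-myosin absolute force
levels inherit the arbitrary 1D registration.

## Problem sizes and numerical choices

Default production sizes, used by the test suite and the acceptance script
alike: 1 s of simulated time per run (1e5 steps), 10 replicates per
condition, 5x5 concentration grids for surrogate fitting; a 16-myosin run
solves a 41-unknown dense system after each of the ~2e3 transition-bearing
steps per second and completes in well under a second of wall time.
Tolerances: 1e-8 relative residual for mechanics; 1e-10 for the analytic
identities; 1e-4 nm bracket tolerance in the ESD fit. Degenerate inputs are
first-class: empty cross-bridge configurations solve to the exact rest
state, a zero-event trace has an undefined (NA, not zero) plateau rate, and
the energy partition at rest is defined as (0, 0).

## Known limitations

* Absolute multi-myosin observables (mean force, per-head ATP rate) depend
  on the 1D registration of the two filaments; only their qualitative
  structure (asymmetry in the two concentration channels, rigor onset,
  bracing-reduced ESD) is robust.
* The fixed-step scheme biases dwell times by ~`k dt / 2` where the
  probability cap engages (extreme high-`[ATP]` corners).
* The hydrolysis-only energy ledger is not a valid bound at early times by
  construction; use the full chemical ledger for conservation checks.
* Titin's slack treatment makes the stiffness matrix configuration-dependent
  (two-branch solve); a smooth nonlinear titin would remove the kink at the
  cost of a nonlinear solve.
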