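---
title: "An integrated model of glutamatergic transmission at a CA1 dendritic spine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An integrated model of glutamatergic transmission at a CA1 dendritic spine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinesim)
```

# Scope and model structure

`spinesim` simulates calcium signalling at a single CA1 pyramidal dendritic
spine in response to presynaptic glutamate release, and the consequences of
the glutamatergic disturbances attributed to soluble amyloid-β oligomers
(AβO): multi-vesicular release, transporter loss, elevated ambient
glutamate, astrocytic glutamate release, receptor internalisation and
slowed receptor desensitisation.  The model couples four stages:

1. **Glutamate field.** Vesicular release at the cleft centre, radial
   diffusion through the 20-nm cleft, escape into a tortuosity-hindered
   extrasynaptic porous medium with first-order transporter uptake.
2. **Receptor kinetics.** Deterministic state-fraction ODEs for
   subtype-specific eight-state NMDARs (NR2A, NR2B) and a seven-state
   AMPAR, driven by the local glutamate concentration of each receptor
   population's zone, with Q10 temperature scaling to 34 °C.
3. **Membrane electrics.** A spine-head/dendritic-shaft two-node circuit
   joined by the 157 MΩ neck resistance, with Jahr–Stevens magnesium block
   of the NMDAR and Hodgkin–Huxley-type voltage-dependent calcium channels
   (VDCC).
4. **Calcium dynamics.** Four well-mixed compartments (PSD, cytosol, neck,
   shaft) with GHK-form receptor and VDCC influx, saturable PMCA/NCX
   extrusion, an immobile endogenous buffer and nearest-neighbour
   diffusional exchange.

A downstream CaMKII state-transition stage (calmodulin loading, CaMKII
activation, autophosphorylation, PSD translocation, anchoring on NR2B
tails) converts the spine-head calcium transient into the four readouts
that gate early long-term potentiation (LTP).  Latin-hypercube/PRCC global
sensitivity analysis and ensemble-MCMC calibration against
backpropagating-action-potential (bAP) evoked transients close the loop.

The control condition is 1500 glutamate molecules per release, 0.5 mM
transporters, 0.25 µM resting extrasynaptic glutamate, and receptor counts
{12 sNR2A, 8 sNR2B, 3 pNR2B, 8 eNR2B, 85 sAMPAR, 20 eAMPAR/µm²}.

# Geometry

The spine head is a hemisphere of 0.1 µm³ (radius 363 nm); the synaptic
cleft is a flat cylinder of the same radius and 20 nm height; the PSD
occupies 10% of the head volume.  Membrane zones are concentric: synaptic
(0–150 nm from the cleft centre), perisynaptic (150–365 nm), extrasynaptic
beyond.  Zone boundaries are half-open below and closed above — the source
description does not state a convention, and the choice only affects
measure-zero inputs.  The neck (0.5 µm × 0.1 µm radius) and shaft
(1 µm × 0.5 µm radius) are cylinders; neck dimensions are typical CA1
values and freely configurable, while the electrical neck resistance is an
independent parameter (157 MΩ).  Derived surface-to-volume ratios must lie
in the validity windows of the calcium calibration data (4–20 µm⁻¹ spine,
1–4 µm⁻¹ shaft) unless `force = TRUE`.

# Glutamate field

The release of `G0` molecules is an instantaneous point source at the
cleft centre.  The field solver is a conservative finite-volume
discretisation of the radially symmetric diffusion equation with two
regimes: the cleft slab (free diffusion coefficient `D_glu`) and, beyond
the rim, a hemispheric porous medium with effective diffusivity
`D_glu/λ²`, extracellular volume fraction α and uptake rate
`k_on · B_total`.  The rim face uses the geometric slab-mouth opening, so
escape from the cleft is rate-limited exactly as in disc-source cleft
models.  Crank–Nicolson time stepping with an implicit-Euler warm-up and a
Thomas solve makes the scheme unconditionally stable; with uptake off and
a reflecting outer boundary the discrete solution conserves the released
molecule count to ~1e-9.

Defaults: `D_glu` = 0.4 µm²/ms at 25 °C (Q10 1.3), λ = 1.4, α = 0.15,
`k_on` = 10 mM⁻¹ms⁻¹ at 23 °C (Q10 3), B_total = 0.5 mM.  Receptor
populations sample the field at representative locations: synaptic at
75 nm (mid-PSD), perisynaptic at 315 nm (outer annulus), extrasynaptic at
a path distance of cleft radius + head radius + neck length (1.23 µm) —
the geometric path from the release site over the back of the head and
down the neck to the shaft.  The perisynaptic point sits in the outer
annulus rather than at the midpoint because perisynaptic NR2B receptors
flank the PSD edge where the astrocytic transporter sheath begins; at this
location full transporter removal raises the perisynaptic peak by
≈2.8 µM and the extrasynaptic peak by ≈1.4 µM for a single release,
while the synaptic peak is untouched — matching the reported transporter
sensitivity pattern.  Both radii are configuration entries.

Superposition of cached single-release impulse responses builds arbitrary
train traces; uptake is linearised (pseudo-first-order), so the
release-evoked component is exactly linear in `G0`.  The astrocytic
protocol applies a square extrasynaptic pulse without touching the cleft.

# Receptor schemes

The NMDAR scheme has eight states — unbound, singly and doubly bound, a
slow and a fast desensitised state, two pre-open intermediates, open —
and the AMPAR seven (three closed binding states, open, three
desensitised).  Topologies are declared as transition tables in the
configuration, so alternative wirings can be swapped in without code
changes.  All rates live at their reference temperatures (23 °C for
receptor kinetics) and are Q10-scaled at scheme build time; because one
Q10 class scales every NMDAR transition uniformly, steady-state
occupancies are temperature-invariant.

The exact published rate tables the original study used are not in its
main text, so the package's defaults are set in two steps.  The
*equilibrium constants* of the gating and desensitisation branches are
fixed analytically so that the steady-state dose–response reproduces the
reported saturating open fractions (0.08 NR2A, 0.02 NR2B) and the common
desensitised plateau (0.81): relative to the doubly-bound state the branch
weights are chosen as 40.5 + 40.5 (desensitised), and gating weights
4 + 6 + 8 (NR2A) versus 6 + 10 + 2 (NR2B).  The *absolute magnitudes* are
in the literature range for the two subtypes — NR2B binds glutamate more
tightly (Kd 0.6 µM vs 2.5 µM) and deactivates more slowly — with binding
speed and desensitisation entry/recovery rates calibrated at the
whole-model level (below).  Desensitisation inhibition multiplies the two
entry rates by `1 − f`, `f ∈ [0, 1]`.

Receptor ODEs are linear in occupancy with a glutamate-bilinear generator
`Q(glu) = Q0 + glu·Q1`; the occupancy simplex is preserved by
construction and asserted to 1e-8 in tests.

# Electrics

Both membrane compartments are electrically tiny: the spine head's ~8 fF
against the 6.4 nS neck conductance gives a microsecond RC time, far
below every chemical timescale.  The spine potential is therefore solved
**quasi-statically** at every integrator stage, while the shaft node
integrates with a 10 pF effective capacitive load standing for the
adjacent dendrite, giving a ~20 ms membrane time constant and realistic
temporal summation of EPSCs across a train.  The charge-balance residual
of the quasi-steady node is identically zero; the engine's electrical
solution is cross-checked against a full capacitive two-node integration
(deSolve) in the test suite.

Magnesium block uses the standard extracellular-Mg sigmoid
`1/(1 + [Mg] e^{−0.062V}/3.57)`; the VDCC activation gate is first-order
with `m∞(V) = 1/(1+e^{−(V+10)/6})`, τ = 1 ms at 23 °C (Q10 3), open
probability `m²`.  A bAP is an imposed double-exponential command clamped
onto the shaft (100 mV amplitude, 0.3/1.2 ms rise/decay); the spine
follows through the neck and can only attenuate.  Pairing protocols clamp
both compartments to the configured pairing potential for the duration of
the train.  The default pairing command is −20 mV: at a full 1-s 0 mV
clamp the GHK influx drives the four-compartment calcium system into the
millimolar range where buffering and extrusion saturate and the
subunit-ratio dependence of the downstream cascade disappears; −20 mV
(Mg unblock 0.27 versus 0.044 at rest) keeps pairing transients in a
regime with clear ratio dependence.  Both the command and the clamp
strength are configuration entries.

Leak conductances (0.05 nS spine, 0.5 nS shaft) were chosen so that a
single-pulse spine EPSP stays below the reported 5 mV ceiling with 85
synaptic AMPARs and the 20-ms astrocytic pulse produces the reported
4–6 mV shaft depolarisation from the low-density extrasynaptic AMPAR
complement.

# Calcium dynamics

Each compartment carries free calcium and buffer-bound calcium.  Influx
routes follow receptor location: synaptic NMDARs into the PSD,
perisynaptic into the cytosol, extrasynaptic and shaft VDCCs into the
shaft.  Unitary calcium flux is GHK with a single-channel permeability
`P_Ca` = 2.56e-14 cm³/s, calibrated so that one NR2A-NMDAR at saturating
resting glutamate and −70 mV passes the reported 580 ions/s (NR2B then
passes ≈145 ions/s against the reported 160).  Extrusion is Hill-type
PMCA (high affinity, Km 0.4 µM) plus a fast low-affinity NCX (Km 20 µM,
turnover 2 ions/ms), scaled by membrane area, density and a pump Q10 of 3;
a constant leak influx balances the pumps *and* the tonic
resting-glutamate NMDAR trickle at the resting calcium of 75 nM, so an
unstimulated simulation is a fixed point.  The immobile buffer
(60 µM spine / 40 µM dendrite, Kd 3 µM) and first-order inter-compartment
exchange (`D_Ca_eff` 0.15 µm²/ms over geometric couplings) complete the
system.  The spine-head readout is the volume-weighted mean of the PSD
and cytosol compartments.

Pump densities, buffer levels and effective diffusivity are exactly the
parameter class the original study estimated by MCMC (its posterior means
are unpublished).  The package's defaults were therefore calibrated
against the printed figure-level observables — control HFS spine peak
2.9 µM, full sNR2A-desensitisation-inhibition peak 17.9 µM, G0 = 10,000
peak 4.8 µM, astrocytic shaft peak 0.087 µM — and all four land within
±25% of the printed values.  The calibration surface is exposed through
the `inference` functions, so users can re-estimate the ten-parameter set
against their own transient features.

**Known limitation.** The post-peak plateau of the G0 = 10,000 HFS run
settles near 1.7–1.9 µM, above the reported 0.5–1.2 µM band.  The
late-train influx is pinned by the steady-state open and desensitised
fractions at the time-averaged synaptic glutamate (≈7 µM, essentially
saturating), which are themselves constrained observables; sweeps over
binding speed (2–5×), glutamate affinity (Kd 2.5→50 µM) and clearance
shape showed that lowering the plateau breaks either the
desensitisation-inhibition peak ratio or the steady-state dose–response.
The corresponding assertion in the test suite is expected to fail and is
retained deliberately.

# Numerical core

The coupled system (46 receptor states, shaft potential, two VDCC gates,
8 calcium states, 6 cumulative influx counters) is integrated by a
fixed-step classical RK4 core in C++ with dt = 10 µs; glutamate traces
are sampled at dt/2 so stage times fall on samples.  The fastest retained
rates (gating ≈ 13 ms⁻¹, binding at the synaptic spike ≈ 40 ms⁻¹) keep
λ·dt well inside the RK4 stability region, and halving dt changes HFS
peak readouts by < 0.5%.  The receptor kinetics are cross-validated
against `deSolve::lsoda` at rtol 1e-8, and a bookkeeping audit (pumps and
buffers disabled) verifies that cumulative influx equals total calcium
accumulation to 0.5%.  Whole-model problem sizes used throughout the
package's tests and examples: 1-s trains (100 pulses HFS), 200-row LHS
designs, 20-walker/60-step ensemble chains — each full simulation runs in
well under a second.

# CaMKII stage

The cascade is a *structural* reimplementation of the staged scheme the
calcium model feeds — the original holoenzyme model's parameters are
outside the source study — with mass-action ODEs: two-lobe CaM loading
(lobe rates quadratic in Ca), Ca₄CaM binding to CaMKII,
autophosphorylation whose rate is multiplied by the active-subunit
fraction (a quadratic approximation to the intra-holoenzyme neighbour
requirement), PSD translocation, and anchoring on NR2B tails with a
saturable capacity of 6 subunit slots per NR2B.  CaM and CaMKII totals
are conserved identically.

Rates are calibrated so the documented qualitative behaviours hold under
1-s pairing HFS: all four readouts blocked at NR2A:NR2B ratios of 6:14
and below, an interior optimum of CaMKII–NMDAR complex formation near
15:5 (≈1.7× control), decline toward 19:1 as the anchoring capacity
collapses, zero complex without NR2B, and silence for sub-threshold
(single-pulse) calcium.  The CaM lobe half-activation points (165 and
223 µM with quadratic lobe kinetics) are operating-range choices matched
to this model's pairing-calcium scale, not literature affinities; the
supralinearity (≈Ca⁴ from sequential lobes × quadratic
autophosphorylation) is what produces the blocking threshold.

# Sensitivity analysis and calibration

`lhs_design()` stratifies each of the fifteen factors uniformly over its
documented range (integer factors rounded); `prcc()` rank-transforms,
partials out the other factors by the precision-matrix route on the rank
correlation matrix, and reports t-approximate p-values with
`df = n − 2 − (k − 1)`.  A brute-force rank-residual regression oracle
agrees to 1e-10.  `sensitivity_experiment()` runs the full simulator per
design row (failures recorded and excluded) and masks the table at
|PRCC| > 0.5, p < 0.05.  At n = 200 under LFS, `G0` is strongly positive
on the spine calcium peak while transporter concentration and
extrasynaptic AMPAR density are null — the documented pattern.

`mcmc_calibrate()` samples the ten calcium-handling parameters (VDCC,
PMCA, NCX densities and buffer totals for spine and dendrite, plus one
shared buffer kinetic pair — one defensible reading of an ambiguous
ten-parameter list) with a Goodman–Weare stretch-move ensemble in
log-space under log-uniform priors (±10× defaults) and a Gaussian
likelihood on four bAP transient features: amplitude and 1/e decay time
for spine and dendrite, extracted after a 2-ms boxcar that mimics
indicator equilibration and removes the sub-millisecond free-calcium
spike preceding local buffer equilibration.  Synthetic targets generated
from known parameters stand in for the unavailable experimental dataset;
the seeded recovery experiment covers ≥ 8/10 truths with 95% intervals.
With four features and ten parameters the posterior is intentionally
wide in the directions the data do not constrain; the recovery criterion
is interval coverage, not point identification.

# What the synthetic data do and do not show

The generator-side choices — deterministic population-mean receptors, an
instantaneous point release, well-mixed compartments, an isolated
two-node electrical skeleton, synthetic bAP targets produced by the model
itself — mean that passing tests demonstrate internal consistency with
the documented behaviours of the modelled spine, not agreement with any
new experimental recording.  Stochastic channel gating, ER/mitochondrial
stores, mobile exogenous buffers, GABAergic input and full dendritic
cable structure are all out of scope.
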