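---
title: "Cardiogenic airflow, pendelluft and gas mixing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cardiogenic airflow, pendelluft and gas mixing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pendelluft)
```

# The problem

The beating heart shakes the lung. These cardiogenic oscillations (CO)
drive measurable airflow in the airway tree — including *pendelluft*, gas
sloshing between sibling lung regions through their shared bifurcation
with no net transport to or from the trachea — and may contribute to gas
mixing whenever tidal ventilation is weak or absent (apnea, breath-holds,
expiratory pauses). `pendelluft` implements, end to end and on fully
synthetic data with known ground truth, the measurement-and-modelling
chain needed to quantify this: double-gated 4D lung imaging surrogates,
cross-correlation velocimetry, expansion-to-flow conversion by
continuity, bulk/pendelluft flow decomposition, and a Lagrangian
gas-tracer transport model that turns measured flows into multi-breath
washout curves under four states — `DIFF` (molecular diffusion only),
`CARD` (cardiogenic oscillations only), `VENT` (mechanical ventilation
only) and `BOTH`.

# Synthetic data: what it emulates and what it does not

All inputs are generated in code; every generator is deterministic in its
seed and records its parameters, so downstream stages can always be
tested against ground truth.

**Airway tree** (`generateAirwayTree`). A full binary tree of straight
cylinders, radius and length contracting geometrically per generation,
branching planes rotated golden-angle-wise with seeded jitter. With
`radiusRatio = 0.83` and a 0.6 mm trachea, a generation-14 terminal has a
diameter of about 88 µm — the scale at which airway segmentations of
mouse lungs typically end. The tree is loosely space-filling but makes no
attempt at lobar anatomy or monopodial (mouse-like) branching; nothing
downstream depends on metric realism beyond segment lengths, radii and
topology.

**Regional expansion field** (`generateExpansionField`). Tissue regions
are scattered around terminal airway end points. Each region's volume
trace is `V0 * (1 + vent(t) + card(t))`:

* the ventilation component follows a pressure-controlled ventilator with
  120 ms inspiration and 280 ms expiration (400 ms cycle, 150 breaths per
  minute): an exponential rise toward the inflation plateau and an
  exponential decay toward PEEP, made exactly periodic by solving for the
  cycle fixed point (`ventilationWaveform`). Time constants default to a
  quarter of each phase duration, which reaches ~98 % of the plateau —
  ventilator-like without being a fit to any particular device. Small
  per-region amplitude spread (10 %) and time-constant jitter (4 ms s.d.)
  emulate compliance/resistance heterogeneity; the time jitter is what
  gives mechanical ventilation its small but non-zero pendelluft.
* the cardiac component is a sinusoid at three times the ventilation
  frequency (the heart/ventilation rate ratio; configurable, e.g. 3.07 to
  decorrelate the two cycles at the cost of a longer composite period)
  whose amplitude decays as `exp(-d / lambda)` with distance `d` from a
  heart locus, and whose phase lags by `phaseLagRate * d`. The decay
  emulates the observed localization of cardiogenic tidal volume near the
  heart; the travelling phase emulates tissue being displaced away from
  the beating heart, which is what makes the cardiac field redistribute
  gas (pendelluft) rather than merely pump it. Defaults
  (`lambda = 2 mm`, `0.8 rad/mm` at whole-tree scale) were chosen once as
  physiologically plausible for a ~10 mm mouse lung and are not fitted.

When a tidal-volume target is requested the whole fractional component is
rescaled linearly, so the target is met exactly up to floating point.

**Speckle phantoms** (`generateSpeckleVolumePair`). Band-passed Gaussian
noise (difference of Gaussians, blob scale ~4-8 voxels, 15 µm voxels) is
warped through a known displacement field with periodic trilinear
interpolation, `deformed(x) = reference(x - u(x))`. Periodic warping
makes integer shifts exact circular rolls, which is what lets the
velocimetry tests demand exact recovery. Real gated CT differs in every
photometric respect (contrast, artefacts, non-periodic boundaries), so
passing phantom tests demonstrates correctness of the estimator, not
robustness to imaging physics.

**Acquisition log** (`generateAcquisitionLog`). Frame times at 50 fps,
ventilation triggers at the 400 ms period, R-peaks quasi-periodic with
configurable jitter, and a pressure trace cycling between 2 cmH2O (PEEP)
and 10 cmH2O (inflation).

# Double gating

`doubleGateFrames` assigns every frame a ventilation phase (elapsed
fraction of its ventilation cycle; bin = `floor(phase * 19)`) and a
cardiac phase (elapsed fraction of its R-R interval; bin =
`floor(phase * 8)`). Design choices where the procedure is under-
determined:

* phase fractions live in `[0, 1)`: a frame exactly on a trigger starts
  the next cycle;
* the pressure filter is strict (`< 4 cmH2O`), applied to cardiac bins
  only, so cardiac-phase data are effectively reconstructed at
  expiratory pressure;
* cardiac phase is defined as R-R *fraction* rather than a fixed time
  offset from the R-peak — robust to heart-rate drift; this is an
  interpretation, recorded here;
* frames before the first trigger are reported unbinnable (never
  silently dropped); frames after the last trigger are phased with the
  median cycle length and flagged.

# Velocimetry and expansion

`crossCorrelateDisplacement` measures one modal displacement per cubic
interrogation region (default 32 voxels wide on a 16-voxel pitch: 480 µm
regions every 240 µm at 15 µm voxels). Windows are mean-subtracted and
correlated in the frequency domain; a plain spatial-domain correlation
serves as the oracle in the unit tests. The estimator is two-pass: the
integer peak offset is found first, the moving window is re-extracted at
that offset, and a 3-point Gaussian fit per axis refines the now
symmetric residual peak. The second pass is what makes integer
displacements exact; single-pass sub-voxel fits on cross-window peaks
carry an asymmetry bias of ~0.1 voxel. Equal maxima break toward the
smallest offset norm. Flat (zero-variance) windows and windows not fully
inside the mask are flagged invalid rather than returned as zero.

`expansionFromDisplacement` computes the fractional volume change as
`det(I + grad u) - 1`, with gradients from central differences on the
region lattice (one-sided at edges and next to invalid regions). The
determinant is exact at finite strain and reduces to the divergence for
small strains; either reading of "local gradients" is therefore
honoured, and any rigid translation gives exactly zero. The definition
used is recorded in the grid's metadata.

# From expansion to airflow

Each region is assigned to its nearest supplying airway (terminal
segments; ties to the lower id). The terminal flow is the time
derivative of the summed assigned-region volumes — positive while the
regions inflate, i.e. positive flow points from trachea to periphery.
On uniform phase grids the derivative uses the 5-point (4th-order)
periodic central stencil: at 19 phases per cycle the 3-point stencil
attenuates a pure sinusoid by 1.8 %, while the 5-point form is exact to
0.04 %, comfortably inside the 1 % the closed-form tests demand.
Non-uniform grids fall back to locally weighted 3-point differences.
Flows then propagate rootward by continuity (`Q_parent = Q_child1 +
Q_child2`, incompressible gas), so the root trace is the total tracheal
flow and equals the lung-volume derivative by construction.

At a bifurcation with parent flow `Q_A` and daughter flows `Q_B`, `Q_C`
(all in the same sign convention), the decomposition is

* total internal flow `Q_tot = |Q_A| + |Q_B| + |Q_C|`,
* bulk flow `Q_bulk = |Q_A + Q_B + Q_C|`,
* pendelluft `Q_pend = Q_tot - Q_bulk >= 0`.

With the trachea-to-periphery sign convention these three formulas
reproduce the canonical regimes: `(q, q/2, q/2)` is pure bulk,
`(0, q, -q)` pure pendelluft. `aggregateFlowDecomposition` averages each
component over the cycle by trapezoidal integration divided by the cycle
duration (ml/s) and sums over *all* bifurcations for whole-tree totals
(whether a generation range should be excluded is not determined by the
source procedure; summing everything plus reporting a per-generation
breakdown in `params$perGeneration` keeps both readings available).
Continuity is asserted at every bifurcation (relative tolerance 1e-6,
configurable for velocimetry-derived flows, which are exact only by
construction on synthetic fields).

# The gas-tracer transport model

The tracer model runs on a simplified geometry: every airway a straight
cylinder; beyond each terminal a *trumpet* — a 1-D section whose total
cross-sectional area grows toward the periphery, piecewise-constant per
generation — ending in a well-mixed acinar compartment with the area of
the last generation. The bundled per-generation table
(`makeTrumpetTable`) is synthetic: a self-similar rule (airway count x2,
diameter x0.85, length x0.8 per generation) chosen to satisfy the
defining trumpet property (non-decreasing area); published morphometric
tables can be substituted directly as they share the same three-column
format.

**Advection.** Tracers are massless and carry cylindrical coordinates
(containing element, axial `z`, relative radius `r/R`, azimuth). The
axial velocity is a Poiseuille profile on the local mean:
`u = 2 Q(t)/A(z) * (1 - (r/R)^2)`, with `Q` linearly interpolated in
time (periodic over the cycle) and, inside trumpets, the quasi-1D
continuity scaling `Q/A(z)` with the parabolic shape retained on the
local radius (the in-trumpet profile is not otherwise determined).
Integration is 4th-order Runge-Kutta; element-boundary crossings are
located by linear interpolation within the step and the remaining step
time is spent in the new element. Advection changes only `z`. The
parabolic-profile assumption is justified for the mouse by Womersley
numbers below 1; `womersleyNumbers` computes them and `runTransport`
warns when the dominant frequency pushes any element to 1 or above (the
trachea sits right at the boundary at cardiac rates).

**Routing.** A tracer crossing a bifurcation is assigned to a candidate
airway with probability proportional to the flow carrying gas away from
the junction, keeping its relative radius; the azimuth is randomized
(only relative radius is constrained by the procedure; the azimuth
choice is recorded here). If, transiently, no candidate carries flow
away, the tracer is held at the junction for the remainder of the step
and the event is counted.

**Trachea boundary.** The inward volume flux at the opening is
integrated in tracer quanta; each whole quantum inserts one fresh Type B
tracer at a uniformly random cross-sectional position within the entry
slug, the fractional remainder carried forward
(`tracheaBoundaryUpdate` keeps the signed arithmetic so negative inflow
depletes the accumulator). The simulation driver integrates only the
*inward* (positive) part of the root flow: integrating the signed flux
would, over any periodic breath, cancel to zero net volume and inject no
fresh gas after the first breath while resident tracers keep leaving —
no washout could occur. Tracers advected out through the opening are
removed and counted by type.

**Compartments.** Tracers advected across a trumpet's distal end join
the compartment tally and are no longer advected or diffused. Outward
terminal flux accumulates and releases one tracer per whole quantum,
type sampled in proportion to the tally composition, re-entering at the
trumpet end over a uniform cross-section. A release requested from an
empty compartment releases nothing and is logged.

**Diffusion.** Random walks: each advection step is divided into
`subSteps` (default 100) sub-steps; per sub-step a tracer moves
`|N(0, sigma)|` in a uniformly random 3D direction with
`sigma^2 = 6 D tau`. The printed step scale "6Dt" is dimensionally
ambiguous as a standard deviation; reading it as the *variance*
`6 D tau` makes the simulated mean squared displacement obey the 3D
Einstein relation `MSD = 6 D t`, which the tests verify directly; the
choice is configurable. `D` defaults to 0.23 cm²/s, the self-diffusivity
of nitrogen at body temperature. Wall crossings reset the direction
randomly into the interior half-space at the collision point and
continue with the remaining length (20 redraws, then the sub-step
remainder is forfeited and counted). A sub-step reaching a bifurcation
routes among the three adjoining airways by cross-sectional area ratio.

**Diffusive boundaries.** Two boundary fluxes need a counter-flux that a
pure removal/tally scheme lacks. At the trachea opening, a tracer
diffusing out is exchanged for a Type B tracer at the mirrored position:
the atmosphere is a fresh-gas reservoir, the net diffusive volume flux is
zero, and one expiration plus one injection are counted. Without this,
the `DIFF` state would contain no fresh gas at all and the CARD:DIFF
concentration ratio would be undefined. At the acinar mouth, a tracer
diffusing in joins the tally and one tracer sampled from the tally
returns at the mirrored position — bidirectional diffusive exchange with
zero net volume. Without it the compartments are one-way diffusion
sinks: in a ventilation-only test run they swallowed ~70 % of each tidal
volume permanently while the trachea injected without bound. Advective
absorption and release are unchanged by either exchange.

**Accounting.** At every step,
`in-airways + in-compartments + expired = seeded + injected`, exactly;
the 40-cycle combined-state test checks the identity at all 8000 steps.

# The washout study

`runWashoutState` seeds tracers uniformly (density `1/quantum`
everywhere, all Type A), runs the transport model for `nCycles`
ventilation cycles, and samples the lung-resident Type A/Type B
fractions once per cycle at *end inspiration*, operationalized as the
instant of maximum total lung volume (maximum cumulative root inflow);
the flow-free states use the same clock for comparability. The
concentration denominator is the whole model domain (airways plus
compartment tallies). `BOTH` is the linear superposition of the
ventilation-only and cardiac-only terminal flow traces before
propagation, mirroring how gating isolates the two components from one
physiological recording. `mixingEnhancementRatio` is the Type B
concentration ratio between paired states (CARD:DIFF, BOTH:VENT);
0/0 samples are flagged, never interpolated.

On the bundled `mouseLikeScenario` (16 terminals, 0.35 ml end-expiratory
volume, 0.2 ml ventilation tidal volume, cardiac regional tidal volume
6.3 % of TLC, ~2000 tracers, 10 cycles) the CARD:DIFF ratio exceeds 1 at
every sampled cycle while BOTH:VENT stays within a few percent of 1 —
the qualitative ordering the model is built to probe. At this reduced
scale molecular diffusion equilibrates the small domain within about one
breath, so the CARD:DIFF ratio saturates near its plateau by the first
sampled cycle rather than climbing visibly over many breaths; the tests
therefore assert the ordering and its persistence, not a growth shape.

# Problem sizes, tolerances and limitations

* Scenario sizes (5 tree generations, ~2000 tracers, 10 cycles,
  `dt = 2 ms`, 100 diffusion sub-steps) are the package's desk-scale
  defaults; they resolve the cardiac cycle with ~65 steps and keep the
  sub-step length below a fifth of the smallest airway radius.
* Monte-Carlo tests use 3 binomial standard errors; closed-form
  transport tests use the analytical tolerances stated inline (1 % for
  cross-sectional means at 1e4 tracers, 5 % for the MSD slope).
* Continuity tolerance 1e-6 (relative) on synthetic flows.
* The model deliberately excludes: pressure/resistance/compliance
  dynamics (flows are inputs, not solved); gas exchange across the
  air/blood barrier; turbulence, secondary flows and skewed profiles at
  bifurcations (human-scale effects); Taylor-dispersion closures
  (dispersion emerges from the resolved profile plus radial diffusion);
  anatomically accurate lobar geometry.
* Passing phantom and toy-lung tests shows the estimators and the
  transport engine are correct under the stated models; it does not
  certify robustness to real imaging artefacts or real airway anatomy.
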