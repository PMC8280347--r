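---
title: "Methods: desk-scale blunt head-impact reconstruction and ADC correspondence"
author: "coupmap"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale blunt head-impact reconstruction and ADC correspondence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package computes

`coupmap` reconstructs blunt head impacts from fall scenarios at desk scale
and maps the simulated biomechanical fields onto the quantity clinicians
read off diffusion-weighted MRI: the apparent diffusion coefficient (ADC,
units of $10^{-6}\,\mathrm{mm^2/s}$).  The computation runs in two steps,
mirroring the multi-fidelity practice of impact biomechanics:

1. **Fall biodynamics.**  The falling body is reduced to a head rotating
   rigidly about the first thoracic vertebra (T1).  Given the angular
   velocity $\omega$ at ground contact and the T1-to-head-centre lever arm
   $L$, the head's centre-of-mass speed is $v = \omega L$ and its kinetic
   energy is
   $KE = \tfrac12 m (\omega L)^2 + \tfrac12 I_c \omega^2$.
2. **Impact biomechanics.**  The head, carrying that rigid-body velocity
   field, strikes a fixed rigid hemispherical object.  An explicit
   central-difference finite-element solver on average-nodal-pressure
   (ANP) linear tetrahedra integrates 20 ms of contact, producing time
   histories (contact force, centre-of-mass displacement, kinetic and
   per-region internal energy, head acceleration) and per-element extremum
   envelopes of the injury measures.

The correspondence step then compares, along the coup–contrecoup line
(impact point through the head centroid to the opposite cortex), the depth
over which $|\Delta\mathrm{ADC}|$ from the gray/white-matter baseline of
$750$ exceeds a significance threshold with the depth over which the
simulated effective strain rate exceeds $250\,\mathrm{s^{-1}}$ (focal coup
injury with skull indentation) or the tensile pressure drops below
$-90\,\mathrm{kPa}$ (coup–contrecoup injury).

# The reduced fall model

Only the head is retained; a full articulated multi-segment body model is
out of scope.  Anthropometry defaults are a 50th-percentile adult head:
mass $m = 4.3$ kg, centroidal inertia about the swing axis
$I_c = 0.018\ \mathrm{kg\,m^2}$, lever arm $L = 0.2$ m.  With these, the
two case presets (case 1: $\omega = 30$ rad/s onto a 15 mm radius object;
case 2: $\omega = 15$ rad/s onto a 60 mm object) give impact kinetic
energies of 85.5 J and 21.4 J.  Both the translational and the rotational
term are included; the rotational term contributes about 9%, which is why
the energies sit slightly above the round figures of roughly 80 J and 20 J
that the translational picture alone suggests.  Neck loads during contact
are omitted — the contact force dominates over 20 ms — and gravity is
applied during the FE stage as a body force along the impact direction.

```{r}
library(coupmap)
impact_state(case_preset(1)$condition, anthropometry())
```

# The phantom and its mesh

The anatomical head is replaced by a layered ellipsoidal phantom: nested
shells of cortical bone (4 mm), cancellous bone (3 mm) and CSF (3 mm)
around a brain interior with a single central ellipsoidal ventricle.
Outer semi-axes default to 0.10/0.085/0.075 m.  Meshing is a deterministic
Kuhn (Freudenthal) six-tetrahedra-per-cube lattice clipped to the outer
ellipsoid; every element receives exactly one region label from the nested
shell containing its centroid.  The lattice is face-conforming by
construction, the boundary of the clipped set is a closed surface (Euler
characteristic 2), and all tetrahedra share the fixed Kuhn quality
(minimum dihedral angle 45°).  The default 12 mm edge length yields about
9,300 elements — deliberately desk scale; multi-million-element anatomical
meshes and their HPC runs are not reproduced, and all full-model field
magnitudes are treated as trend references only.

The stair-stepped boundary overestimates the true surface area and makes
the one-element-thick shells irregular; consequences are discussed under
*Limitations*.

# Constitutive models

All tissues share the volumetric law $p = K \ln J / J$.  Deviatorically:

| region | model | defaults |
|---|---|---|
| brain | neo-Hookean + Prony relaxation | $\rho=1040$, $K=2.19$ GPa, $G_0=10$ kPa, $g_1=0.8$, $\tau_1=10$ ms |
| CSF / ventricle | neo-Hookean, water-like | $\rho=1000$, $K=2.19$ GPa (speed of sound of water), $G_0=100$ Pa |
| cortical bone | J2 elastoplastic | $\rho=1900$, $E=15$ GPa, $\nu=0.22$, $\sigma_y=90$ MPa, $H=1$ GPa |
| cancellous bone | J2 elastoplastic | $\rho=1200$, $E=1$ GPa, $\nu=0.24$, $\sigma_y=30$ MPa, $H=1$ GPa |

These are literature-typical values; the package's verification is
property-based (energy conservation, wave speeds, analytic benchmarks),
not parameter-exact.  Brain/CSF viscous relaxation uses the midpoint
exponential recurrence on the deviatoric Kirchhoff stress, exact for
piecewise-constant stress increments: the instantaneous response is
$G_0$, the fully relaxed response $(1-\sum_i g_i) G_0$.  Bone plasticity is
finite-strain J2 radial return on the elastic left Cauchy–Green tensor
with linear isotropic hardening, which leaves genuine permanent
deformation after unloading — the mechanism behind the residual skull
indentation of case 1.

# The explicit solver

* **Integration.**  Central difference with a lumped (row-sum) mass
  matrix.  The step is `safety * min(h_char / c_d)` with
  $c_d=\sqrt{(K+4G_0/3)/\rho}$ and `h_char` the element's minimum
  altitude; the default safety fraction is 0.8.
* **ANP tetrahedra.**  Each node's volume ratio $\bar J$ is the
  reference-volume-weighted average of adjacent-element $J$, restricted
  within each material group (no averaging across skull/CSF/brain
  interfaces, which would create spurious interface stiffness); nodal
  pressure is $K \ln \bar J/\bar J$ and the element volumetric stress is
  the mean of its four nodal values.  This relieves the volumetric locking
  of standard linear tetrahedra: on the near-incompressible cantilever
  benchmark ($\nu = 0.4995$, 6 elements through the thickness) ANP lands
  within 10% of the Timoshenko reference while standard tetrahedra
  under-deflect by more than 75% — an error reduction well above the 3×
  the package asserts in its tests.
* **Contact.**  Frictionless nodal penalty against the rigid sphere:
  $f = k_p A_\mathrm{node} \delta$ outward along the radial direction,
  with $A_\mathrm{node}$ the node's share of reference boundary facet
  area.  The default $k_p = 10^{12}\,\mathrm{N/m^3}$ makes the impactor
  effectively rigid — contact compliance is left to the discretized head
  structure — and is the stiffest round value inside the explicit contact
  stability limit at the default mesh.
* **Energy accounting.**  Internal work accumulates
  $\tfrac12(\sigma_n + \sigma_{n-1}) : D_{n-1/2}$ per step, with the rate
  of deformation built from the midpoint relative deformation gradient.
  Both midpoints matter: an end-of-step pairing accumulates a secular
  error against near-CFL ringing modes (and against residual stresses
  under rigid rotation) of tens of percent over 20 ms, while the midpoint
  pairing closes the budget
  $KE_0 + W_\mathrm{grav} = KE + W_\mathrm{int} + E_\mathrm{contact}$
  to about 0.1% of the initial kinetic energy on the case runs.  The
  solver aborts with a diagnostic if the budget grows by more than 5%
  without energy input.
* **Degenerate inputs.**  Zero-volume reference elements, element
  inversion ($J \le 0$), non-positive averaged $\bar J$, and a contact
  node coinciding with the impactor centre all raise immediately with the
  element or node identified; there is no silent clipping anywhere in the
  package (including negative synthetic ADC values, which raise rather
  than clip).

# Injury measures and envelopes

Strains are Green–Lagrange $E = \tfrac12(F^\top F - I)$; stresses Cauchy;
the strain rate is the symmetrized velocity gradient.  Effective
quantities use $\sqrt{\tfrac32\, X^d : X^d}$.  Pressure is
$-\operatorname{tr}\sigma/3$, compression positive, so the injurious
"minimum pressure" is the most tensile state and is tracked as a
dedicated minimum envelope.  The maximum shear strain rate is the
engineering rate $d_1 - d_3$; this is the definition under which simple
shear reproduces the characteristic ordering max-shear > effective
($0.87\dot\gamma$) > first-principal ($0.5\dot\gamma$).  The product of
strain and strain rate is evaluated instantaneously per step
(effective strain × effective strain rate) and then enveloped.
Dilatational and distortional energy densities accumulate
$\sigma_m\,\mathrm{tr}D\,dt$ and $s : D^d\,dt$ per step.  Envelopes break
extremum ties to the earliest time, and are exported both per element and
as per-region argmax summaries (the time-to-extremum table can be read
either way; both are provided).

Envelopes are refreshed from full-field snapshots (default about 50 over
20 ms) rather than every step; sub-snapshot peaks of rapidly-varying
fields are therefore slightly underestimated, uniformly across cases.

# Synthetic data: what it emulates, and what it does not

The ADC phantom emulates the quantitative structure of clinical maps:
gray/white-matter background at 750, CSF ventricle values drawn in
[3000, 4000], contusion lesions with a hemorrhagic core of uniformly
reduced ADC surrounded by an edema rim of raised ADC tapering linearly to
zero, plus additive Gaussian voxel noise.  The default grid is the
clinical 128×128×45 with 4 mm slice spacing; the in-plane spacing of
1.8 mm is inferred from a 230 mm field of view over a 128 matrix (the
acquisition tables state the field of view but never print the in-plane
ADC spacing).  The case presets plant lesions whose
$|\Delta\mathrm{ADC}| > 200$ extents reproduce the two cases' reported
depth patterns: ~10 mm coup (case 1, change range −450 to +1150), ~30 mm
coup and ~20 mm edema-only contrecoup (case 2, ranges −750 to +950 and 0
to +1100).

Passing the recovery tests on these phantoms shows that the analysis
pipeline measures planted depths to within a voxel under moderate noise.
It does not show robustness to what the generator leaves out: partial
volume and susceptibility artifacts near bone, anatomical heterogeneity
of the baseline, irregular lesion shapes, or registration error between
the image and simulation frames (the package deliberately requires the
caller to supply corresponding coup/contrecoup points in each frame
rather than attempt registration).

Because the case-2 core change of −750 puts the core at the physical zero
of the ADC scale, additive noise there would drive values negative, which
the generator treats as an error; case-2 preset volumes are therefore
generated noise-free, with noise robustness demonstrated on lesions that
leave headroom.

# The correspondence step

Depth of exceedance walks the profile from the cortex entry (the first
unmasked sample), accumulates the first contiguous run satisfying the
criterion, and interpolates the crossing linearly between samples.
CSF-masked samples (ADC ≥ 3000, or non-brain regions of simulated
profiles) are skipped without breaking contiguity.  Two small decisions
deserve note:

* **Sign-change gap bridging.**  Where the negative hemorrhagic core
  meets the positive edema rim, $|\Delta\mathrm{ADC}|$ must cross zero,
  dipping below the threshold over less than a voxel.  When scanning ADC
  profiles the report bridges sub-threshold dips up to twice the
  interpolation-kernel width along the axis; the bare
  `depth_of_exceedance()` default bridges nothing.
* **$\tau_a = 200$.**  The literature reports ranges and depths of
  "significant" ADC change but no numeric cutoff; 200 ×
  $10^{-6}\,\mathrm{mm^2/s}$ (≈4× typical map noise) is this package's
  choice, configurable in `injury_thresholds()`.

Simulated-field depths are measured in the undeformed configuration by
default (sampling positions are a flag away from using the deformed
nodal coordinates).  Detached deeper exceedance runs are reported
separately as `secondary_runs` rather than silently merged.

# Problem sizes and runtimes

The package's default study sizes are chosen so the full loop runs on a
single CPU core: the 12 mm phantom (≈9.3k tetrahedra, ≈8.8k steps of
2.3 µs for 20 ms) takes ~15 s per case; the verification battery (patch
test, 20 ms elastic drift on a ≈5.9k-tet phantom, 1D wave time-of-flight,
Hertz indentation ramp on a 33.6k-tet block, two cantilever runs) about
three minutes in total.  Mesh refinement to 8 mm (31k tets) changes the
case-1 peak contact force by under 1% and leaves every reported trend
unchanged.

# Known limitations

* **No scalp, no fracture, linear contact.**  The phantom has no scalp
  layer and bone failure is plasticity, not fracture.  With a *linear*
  penalty contact the effective contact stiffness grows with the engaged
  area, so the 60 mm impactor always produces a stiffer, shorter contact
  than the 15 mm one; the clinically reconstructed ordering — the focal
  case-1 impact having the *shorter* contact — arises from
  pressure-stiffening through scalp onto locally crushing bone, which
  this model family cannot express.  Contact durations are accordingly
  both shorter than full-model values and ordered the other way; peak
  force and acceleration orderings, the plastic-indentation contrast, and
  the coup–contrecoup tensile-pressure pattern are reproduced.
* **Field magnitudes are trend-level.**  Coarse elements concentrate the
  contact load, so peak accelerations and intracranial pressure extrema
  exceed full-model values severalfold; only orderings and
  threshold-exceedance patterns should be read from them.
* **Stair-step boundary.**  Nodal contact areas on the voxelized surface
  overestimate smooth-surface areas; this folds into the penalty scale
  and is absorbed by the (configurable) stiffness choice.
* **CSF as solid.**  The CSF layer is a near-incompressible solid, not a
  fluid; no fluid–structure interaction, no cavitation.
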