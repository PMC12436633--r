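---
title: "flow4d: models, numerics and verification phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{flow4d: models, numerics and verification phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

flow4d post-processes time-resolved, three-directional phase-contrast MRI
("4D flow MRI") of pulsatile blood pumps and cardiac chambers. The input
is a velocity vector field $u(x, t)$ on a regular voxel grid over the
cardiac cycle, plus magnitude images and a fluid mask that may move with
the pump walls. This vignette describes the quantities the package
computes, the numerical choices behind them, and what the synthetic
verification phantoms do and do not establish.

## The physical quantities

With fluid density $\rho$ and dynamic viscosity $\mu$, the package
computes, per voxel and timeframe:

* **Kinetic energy density** $KE = \tfrac{\rho}{2}(u_x^2 + u_y^2 + u_z^2)$
  in J/m^3^ — where the flow is fast, and when.
* **Velocity-gradient tensor** $\partial v_i / \partial x_j$ in s^-1^, by
  central differences on the voxel grid (below).
* **Viscous dissipation**
  $\phi_v = \tfrac12 \sum_i \sum_j \left[\left(\frac{\partial v_i}{\partial x_j}
  + \frac{\partial v_j}{\partial x_i}\right)
  - \tfrac{2}{3}(\nabla\!\cdot u)\,\delta_{ij}\right]^2$ in s^-2^.
  Its volume integral times viscosity is the **viscous energy loss**
  $E_L' = \mu \sum_i \phi_v V_i$ in W — the extra mechanical work the pump
  spends against friction. The $\tfrac{2}{3}(\nabla\cdot u)\delta_{ij}$
  term is retained even though the fluid is incompressible: the *measured*
  discrete divergence is nonzero (noise, discretisation), and dropping the
  term would silently change the noise response of $E_L'$.
* **Scalar shear stress** $\tau = \mu\sqrt{2\,S_{ij}S_{ij}}$ in Pa, with
  $S_{ij} = \tfrac12(\partial v_i/\partial x_j + \partial v_j/\partial x_i)$
  — a rotation-invariant magnitude of viscous stress in the bulk fluid
  (not a wall shear stress; no surfaces are reconstructed).
* **Turbulent kinetic energy**
  $TKE = \tfrac{\rho}{2}(\sigma_{xx}^2 + \sigma_{yy}^2 + \sigma_{zz}^2)$
  in J/m^3^, from the directional intravoxel velocity variances
  $\sigma_{ii}^2$ (below).
* **Relative stasis** $r_\mathrm{stasis} = 100\, n_\mathrm{stasis}/N_\mathrm{tot}$,
  the percentage of frames with speed strictly below a threshold
  (default 0.1 m/s, the conventional blood-stasis cutoff).

Integrated summaries: cross-sectional flow rate $q = \sum u_N\,\Delta A$,
stroke volume $SV = \sum_t q_t\,\Delta t$, Reynolds number
$Re = \rho q_\mathrm{max} d / (\mu A)$, regional volume integrals over
time, maximum-intensity projections (MIPs) over cycle and view direction,
fixed-width histograms, quartile summaries, and interpolated line
profiles. A recirculation detector sizes flow-separation zones in a duct
from the zero-axial-velocity isosurface.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `rho` | 1089 | kg/m^3 | density of the blood-mimicking water–glycerol mixture |
| `mu` | 3.7e-3 | kg/(m·s) | its dynamic viscosity |
| VENC | 0.7 or 2.0 | m/s | velocity-encoding limit; also sets $k_v = \pi/\mathrm{VENC}$ |
| `stasisThreshold` | 0.1 | m/s | speed below which a frame counts as stasis |
| `histogramBinWidth` | 0.02 | Pa | bin width of the shear-stress histogram |
| frame duration | 0.014 | s | uniform timeframe spacing |
| spacing | 2.0 | mm | isotropic voxel size of the phantoms |

All internal quantities are SI. Files carry acquisition-native units
(VENC in cm/s, frames in ms, spacing in mm); every conversion on read is
logged.

## Gradients at mask boundaries

The velocity gradient uses a central difference where both axis
neighbours are inside the fluid mask. At the mask boundary a central
stencil would reach into the wall or a signal void, so the package falls
back to a one-sided first-order difference when exactly one neighbour is
available, and flags the voxel **invalid** for that axis otherwise.
Invalid voxels are excluded from every derived map, integral and
histogram, and their count is logged and stored in the run manifest:
fabricating wall gradients would bias exactly the quantities ($\tau$,
$E_L'$) that concentrate near walls.

Two consequences worth knowing:

* On fields with zero third derivative (uniform, linear shear, the
  parabolic pipe profile) the central difference is *exact*, which is why
  several verification checks demand machine precision rather than a
  tolerance.
* One-sided differences at the wall are first-order accurate and
  systematically underestimate the wall-adjacent shear. For a Poiseuille
  pipe of radius 11 mm at 2.0 mm spacing this biases the total viscous
  energy loss by about −7% relative to the closed form
  $8\pi\mu L U^2$; the error shrinks under grid refinement (about −1.8%
  at 0.5 mm).

Related: the phantom generator places the pipe axis on a voxel-center
column (the one nearest the grid centre). With the axis on a voxel
*corner* instead, the wall-adjacent voxel ring sits systematically closer
to the wall and the same integral is off by roughly −25% at 2.0 mm. This
is a genuine property of coarse voxelisations of circular sections, worth
remembering when placing analysis planes in measured data.

## Background-offset correction

Phase-contrast velocities carry a smooth spatial offset. It is estimated
from a static acquisition (pump off, zero true velocity): a second-order
3-D polynomial with basis $\{1, x, y, z, x^2, y^2, z^2, xy, xz, yz\}$ is
fitted per velocity component by ordinary least squares over the masked
fluid voxels, then evaluated at *every* voxel — i.e. extrapolated beyond
the static mask — and subtracted from the moving acquisition.

Numerical choices:

* Coordinates are normalised to $[-1, 1]$ per axis before building the
  design matrix; the raw-coordinate quadratic design is badly conditioned
  on millimetre grids and is not offered.
* The frames of the static series are averaged before fitting. The fit
  is linear, so this changes nothing in the noiseless limit and reduces
  the noise variance of the coefficient estimates.
* Plain (unweighted) least squares is used; magnitude weighting is a
  plausible alternative but needs magnitude data that a static velocity
  series does not always carry.
* A rank-deficient design (e.g. a coplanar mask, which cannot pin down
  the $z$-quadratics) is an error naming the deficiency, not a silent
  pseudo-inverse.

On noiseless synthetic offsets the fit/subtract pair is exact to machine
precision, and re-fitting the corrected static data returns coefficients
below 1e-12 m/s. With Gaussian noise of 0.01 m/s over ~10^4^ mask voxels
the worst coefficient error across 20 seeds stays below 0.005 m/s (the
OLS standard error is roughly $0.01/\sqrt{n}$ times a basis-dependent
factor, i.e. an order of magnitude smaller than that bound).

## Turbulence from magnitude attenuation

Intravoxel velocity dispersion attenuates the velocity-encoded magnitude
signal. flow4d adopts the standard Gaussian intravoxel
velocity-distribution model: with turbulence-encoding sensitivity
$k_v = \pi/\mathrm{VENC}$,
$$ |S_\mathrm{venc}| = |S_\mathrm{ref}|\,
   \exp\!\left(-\tfrac12 k_v^2 \sigma_i^2\right)
   \quad\Longleftrightarrow\quad
   \sigma_i^2 = \frac{2}{k_v^2}\,
   \ln\frac{|S_\mathrm{ref}|}{|S_\mathrm{venc},i|}. $$
Published estimators differ in detail (motion-encoding waveform shape
enters $k_v$); the package commits to this form, uses it consistently on
both the generation and estimation side, and verifies the pair is an
exact inverse. Negative variance estimates — expected where true
turbulence is low and noise dominates — are clipped to zero and counted;
no spatial smoothing is applied. Voxels with non-positive magnitude are
flagged invalid and excluded.

## Stasis, histograms, quantiles, time integration

* Stasis uses a **strict** inequality ($|u| <$ threshold), so a voxel
  sitting exactly at the threshold does not count. Voxels absent from the
  fluid mask in any frame (moving walls) are ineligible and excluded —
  their Eulerian time fraction would mix fluid and wall.
* Histograms pool **all valid voxel–frame samples** over the cycle into
  fixed-width bins anchored at zero; percentages are of the pooled
  sample.
* Quantiles use linear interpolation between order statistics
  (`stats::quantile` type 7), fixed for cross-implementation
  reproducibility.
* Stroke volume integrates $q(t)$ with the rectangle rule on the uniform
  frame grid. The cycle is periodic, so the rectangle rule has no
  endpoint bias and the trapezoid rule would give the identical answer;
  the choice is recorded here because it matters for non-periodic
  excerpts.
* The hydraulic diameter of a cross-section defaults to $4A/P$ with the
  perimeter counted from exposed pixel edges. For coarse circular masks
  the staircase perimeter overestimates $P$ (up to the $8R$ vs $2\pi R$
  Manhattan limit), so an explicit geometric diameter can and should be
  supplied where one is known.

## Recirculation-zone sizing

In a duct with declared axial and wall-normal directions, the detector,
per frame: finds the 6-connected set of reversed-flow voxels
($u_\mathrm{axial} < 0$) attached to the inner wall (detached reversed
pockets are ignored and counted); locates the zero crossing along each
wall-normal column by linear interpolation between the sign-changing
voxel pair; reports **height** as twice the maximum wall-normal crossing
distance — the isosurface is assumed to pass through the core of the
recirculation, at half its total height — capped at the duct height; and
reports **length** as the streamwise distance from the declared
inner-corner reference to the furthest sub-voxel zero crossing of the
axial velocity in the first off-wall voxel layer.

Choices the verbal definition leaves open, fixed here: "near the wall"
means the first voxel layer adjacent to the inner wall; length is
measured along the inner wall (not the duct centreline); the factor-2
height convention is applied regardless of surface symmetry; the duct
frame is user-declared, never inferred from the data. Because the layer
sits half a voxel off the wall, a zone whose zero-line meets the wall at
a shallow angle is clipped where the line drops below the layer height —
with zone heights of several voxels the verification phantoms recover
length and height within one voxel spacing, which is the accuracy claim
the package makes.

## The synthetic phantoms: what they show and what they cannot

`generatePhantom()` evaluates closed-form fields at voxel centres
(voxel $(i,j,k)$ centred at $((i,j,k) - 0.5)h$): Poiseuille pipe flow
$u = 2U(1 - r^2/R^2)$ (steady or waveform-scaled), uniform plug flow,
linear shear, solid-body rotation, and a separation duct
$u = U w(t)\,(y - y_0(x))/H$ whose zero-axial-velocity surface is the
prescribed curve $y_0$ by construction. Masks mark voxels whose centre
lies strictly inside the geometry, which keeps the analytic oracles free
of partial-volume ambiguity. Every phantom attaches its ground truth
(flow rate $\pi R^2 U$, dissipation power $8\pi\mu L U^2$, KE integral
$\tfrac{\rho}{2}\tfrac43 \pi U^2R^2L$, wall shear $4\mu U/R$,
recirculation length/height) computed from the closed forms, never from
the grid. Turbulence phantoms encode arbitrary $\sigma$ fields through
the magnitude model above; `addNoise()` adds seeded Gaussian velocity
noise; `injectBackgroundOffset()` plants known polynomial offsets.

These phantoms emulate the *geometry and scale* of a heart-sized pump
acquisition (2.0 mm isotropic voxels, 40 frames of 14 ms, VENC 0.7/2.0
m/s) and give exact oracles for every pipeline stage. They deliberately
do **not** emulate: Rician magnitude noise or k-space effects, phase
wrapping, partial-volume signal at walls, valve signal voids (only
representable as mask holes), unsteady Womersley profiles (waveform
scaling is quasi-steady), or genuine turbulence dynamics. Passing the
phantom suite therefore demonstrates that the *implementation* of each
formula and detector is correct and convergent — not that the metrics are
unbiased on any particular scanner's data.

Problem sizes used by the test-suite and verification runs: pipes of
6–10 × 15 × 15 voxels (up to 49 × 49 at 0.5 mm refinement), separation
ducts of 48 × 18 × 12, turbulence fields of ~5 × 10^3^ voxel-frames,
background fits over ~10^4^ voxels and 20 noise seeds. These sizes put
every oracle comfortably past its asymptotic regime while keeping the
whole suite in seconds; the bundled demo (`makeDemo()`) uses the same
scales.

## Reproducibility machinery

All randomness sits behind explicit integer seeds (`addNoise()`, demo
generation); seeded draws restore the caller's RNG state. `runPipeline()`
writes a manifest with the configuration snapshot, per-stage wall time,
exclusion/clip counts (wrap warnings, clipped $\sigma^2$, invalid
gradients) and an MD5 inventory of every output, and identical
configuration plus inputs reproduce byte-identical CSV/JSON analysis
outputs. Velocities above the VENC trigger a logged wrap warning rather
than silent acceptance.

## Known limitations

* Eddy-current and concomitant-field corrections, phase unwrapping and
  DICOM ingestion are out of scope; inputs are assumed
  scanner-corrected, in m/s, as NIfTI-1 plus a JSON sidecar.
* Eulerian stasis is not meaningful inside moving-wall regions; the
  eligibility rule excludes them rather than reinterpreting them.
* $\phi_v$ is quadratic in gradients and hence noise-amplifying;
  volume-integrated $E_L'$ is the robust comparative quantity, and no
  smoothing is applied anywhere.
* Oblique cross-sections require resampling onto a rotated grid first;
  sections are axis-aligned voxel planes.
* The recirculation detector tracks one wall-attached separation zone;
  it is not a general vortex-core extractor.
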