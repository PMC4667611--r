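---
title: "Pressure, pull-push forces and swimming efficiency from planar velocimetry: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pressure, pull-push forces and swimming efficiency from planar velocimetry: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swimpressure)
```

## The measurement-to-inference chain

Time-resolved particle image velocimetry (PIV) of a freely swimming
animal yields a sequence of planar velocity fields $(u, v)(x, y, t)$
on a regular grid, together with per-frame binary masks of the body.
This package turns those two inputs into (i) gauge-pressure fields,
(ii) body-surface kinematics, (iii) a four-way decomposition of the
surface pressure force, and (iv) Froude-type hydrodynamic
efficiencies of the pulling (suction) and pushing mechanisms of
undulatory swimming.

### Pressure from velocity

The planar momentum balance gives the pressure gradient at every
node,
$$\nabla p \;=\; -\rho\,\frac{D\mathbf u}{Dt} \;+\; \mu \nabla^2
\mathbf u,$$
with the material acceleration $D\mathbf u/Dt = \partial_t\mathbf u +
(\mathbf u\cdot\nabla)\mathbf u$ evaluated by centred differences:
three consecutive frames in time, second-order stencils in space, a
5-point Laplacian for the viscous term. A node is valid only when its
whole space-time stencil is valid; no one-sided fallback is used near
the mask, so body-adjacent values are never contaminated.

The gradient is then integrated along **eight straight rays** (the
four grid directions and four diagonals) running from each node to
the edge of the field of view, where the gauge pressure is known.
Accumulation is by the trapezoidal rule from the boundary inward;
rays that cross a masked or invalid node are discarded; the node's
pressure is the **median** of the surviving rays (an even count
averages the two central values). The median makes the estimate
robust: a single corrupted ray leaves the result unchanged whenever
at least five rays agree, which the test suite checks by
construction. Nodes with fewer than `min_valid_paths` (default 3)
surviving rays are marked invalid and recovered by nearest-valid
interpolation, flagged in the output and counted in the report's QC
block.

Two numerical choices deserve note:

* **Boundary pressure.** The field-of-view edges are taken at ambient
  gauge pressure 0, the appropriate condition for a measurement
  window whose edges sit in quiescent far field. For analytic
  validation flows whose true pressure is *not* ambient at the window
  edge (the Taylor–Green lattice, a truncated Gaussian bump), the
  known edge values can be supplied via the `boundary` argument;
  without them the mismatch is a field-dependent bias that no
  integration scheme can remove, with them the solver converges at
  second order (observed order about 2.2 over $32^2 \to 128^2$).
* **Edge ring.** Centred stencils cannot produce a gradient on the
  outermost node ring, which would invalidate every ray at its seed.
  The ring is closed by copying the gradient from the adjacent
  interior node — first-order, but it affects one trapezoid step per
  ray and leaves the global second-order behaviour intact.

An independent **Poisson oracle** (`poisson_pressure_oracle`) solves
$\nabla^2 p = \nabla\cdot \mathbf g$ with Dirichlet edges and a
Neumann closure $\partial p/\partial n = \mathbf g\cdot\hat{\mathbf
n}$ on mask faces by a direct sparse solve. It shares no code path
with the ray integration and is used in the tests to bound the
disagreement between the two routes (within 2% of the field range on
smooth mask-free cases).

### Body-surface kinematics

The body outline is traced as the 0.5 iso-contour of the binary mask
(sub-cell, via linear interpolation between nodes) and resampled to
**60 control points** at equal arc-length spacing, anchored at the
anterior-most point along the swimming direction. Note that the
iso-contour of a binary raster necessarily sits half a cell outside
the outermost body nodes; tests assert the geometrically correct,
half-cell-dilated perimeter.

Per frame triple (previous, current, next):

* surface velocity `u_body`: central difference of control-point
  positions;
* **BSR** (body surface rotation): the lab-frame angular velocity of
  each segment connecting adjacent control points, by central
  difference of the segment angle with jumps beyond $\pi$ unwrapped;
* **BSV** (body surface vorticity): the fluid vorticity
  $\omega = \partial_x v - \partial_y u$ at the valid node nearest
  each control point, with the search capped at 4 cells so masked
  shadows never pull in dynamically irrelevant fluid.

For solid-body rotation the discrete vorticity equals exactly twice
the angular velocity (the stencil is exact on linear fields), which
is the no-slip link between BSR and BSV.

The swimming frame is fitted from the per-frame contour centroids: a
least-squares line gives the direction $\hat{\mathbf s}$ (oriented
along the net displacement), $\hat{\mathbf j}$ is $\hat{\mathbf s}$
rotated $+90^\circ$, and $U$ is the net centroid displacement
projected on $\hat{\mathbf s}$ over the elapsed time. Index
correspondence across frames is by arc-length position from the
anterior anchor, not by feature tracking — stable for undulating
bodies.

### Four-way force decomposition

Each surface element carries $\mathbf f_i = -p_i \hat{\mathbf n}_i\,
\mathrm dA_i$ with the pressure sampled by bilinear interpolation two
cells outside the surface (mask-adjacent nodes inherit stencil
damage; unresolved points retry outward up to two further cells).
Elements are classified by the sign pair $(\operatorname{sign} p_i,\;
\operatorname{sign} \mathbf f_i\cdot\hat{\mathbf s})$ into forward
pull, rearward pull, forward push and rearward push; the
classification threshold is exactly ambient ($p = 0$, no dead band by
default). Gross thrust is the sum of the forward components, gross
drag of the rearward ones, and the identity
$F_\text{fpull} + F_\text{fpush} - F_\text{rpull} - F_\text{rpush} =
\sum_i \mathbf f_i \cdot \hat{\mathbf s}$ holds to machine precision
on every frame.

In planar mode $\mathrm dA_i = \mathrm ds_i$ and forces are per unit
depth (N/m), the right bookkeeping for an elongated swimmer cut by a
light sheet. In axisymmetric mode a meridional half-profile is
revolved about the symmetry axis, $\mathrm dA_i = 2\pi r_i\,
\mathrm ds_i$ (N), the bookkeeping for a radially symmetric bell
imaged on its mid-plane; the profile must not cross the axis, and a
full-profile uniform pressure integrates to exactly zero force
(projected-area identities are verified in closed form in the
tests).

### Efficiencies

With $T$ the time-averaged gross forward thrust, $U$ the mean
swimming speed and
$$P_\text{lat} \;=\; \sum_i p_i\,(\hat{\mathbf n}_i\cdot\hat{\mathbf
j})\,(\mathbf u_{\text{body},i}\cdot\hat{\mathbf j})\,\mathrm dA_i$$
the rate of work done by the body on the fluid transverse to the
swimming direction, the hydrodynamic efficiency is the Froude-type
ratio
$$\eta \;=\; \frac{T\,U}{T\,U + P_\text{lat}}.$$
The pull efficiency uses only the pulling thrust and the lateral
power restricted to elements with $p<0$ (where the body is pulled
laterally by low adjacent pressure), $\eta_\text{pull} =
T_\text{pull}U/(T_\text{pull}U + P_\text{lat,pull})$, and
$\eta_\text{push}$ analogously for $p>0$. Subset lateral powers add
exactly to the total. Signed local terms are kept: negative
contributions are genuine energy recovery, and no rectification is
applied; a negative *cycle-averaged* $P_\text{lat}$ is reported as-is
with a warning (it signals an input whose lateral energy budget is
conservative, not a numerical fault). All averages are trapezoidal
over a common window spanning an integer number of undulation
cycles.

## The synthetic data generator

No animal recordings ship with the package; every downstream stage is
exercised on synthetic data of two kinds.

**Analytic flows with known pressure** validate the solver
quantitatively: the decaying Taylor–Green lattice (exactly solenoidal,
closed-form pressure), potential flow past a cylinder (masked body,
surface $C_p = 1 - 4\sin^2\theta$, d'Alembert zero net force) and the
Lamb–Oseen vortex (suction core; pressure truth by radial quadrature,
cross-checked against the closed form $p(0) = -\rho\Gamma^2\ln 2/
(4\pi^2 r_c^2)$).

**The synthetic swimmer** emulates the study system: an undulating
slender body (length $L = 0.12$ m, one wavelength on the body,
period $T_p = 0.4$ s) whose midline executes either a *traveling*
wave $y = A(s)\sin 2\pi(s/\lambda - t/T_p)$ at 2.0 body lengths/s —
the coordinated gait — or a *standing* wave $y = A(s)\sin(2\pi
s/\lambda)\cos(2\pi t/T_p)$ at 1.2 body lengths/s — the uncoordinated
gait that a mid-body spinal transection produces. The amplitude
envelope $A(s) = a_0 + a_2 s^2$ grows from 0.002 m at the nose to
0.012 m (0.1 L) at the tail, an order-of-magnitude choice for
anguilliform kinematics; the half-width profile is an ellipse with
maximum 0.006 m.

The flow is **kinematically prescribed**, not a Navier–Stokes
solution, built from two exactly solenoidal element families:

* **Vortex blobs** (Gaussian-core, Lamb–Oseen profile, core 5 mm) at
  the 60 contour segments, with circulation $\Gamma_i = \Gamma_0\,
  \mathrm{BSR}_i\, \mathrm ds_i$ clipped at $3\Gamma_0$ — the no-slip
  correspondence: near-body fluid rotation tracks body surface
  rotation. $\Gamma_0 = 0.025\ \mathrm{m^2/s}$ was calibrated once so
  that the sampled near-surface vorticity is about $2\times$ BSR
  (regression slope $\approx 0.95$), the value the no-slip condition
  demands for solid-body-like surface rotation.
* **Lateral dipole elements** (regularized doublets, core 2.5 mm,
  sunk one core radius inside the body) carrying the
  acceleration-reaction near field of each element advancing at its
  normal velocity. Their strength coefficient $\kappa = 2$ was
  calibrated once so the near-surface normal fluid velocity matches
  the body normal velocity about 1:1. Sinking the cores inside the
  masked region keeps their (spurious) core vorticity away from the
  BSV sampling nodes while preserving the irrotational far field.

Blob circulations follow the body instantaneously, but the dipole
response **lags the kinematics by $T_p/12$**. The lag is the
generator's only irreversibility and it matters: ideal flow is
time-reversible, so a standing-wave flapper would recover every joule
of lateral work and come out *more* efficient than the traveling
swimmer — the opposite of what transection experiments show. A
formation lag is the physical mechanism (boundary-layer vorticity and
separated-flow pressure take a finite fraction of a cycle to build)
by which real flapping loses energy; $T_p/12$ (a 30° phase lag) is a
plausible round value, fixed once and not fitted.

What the generator does *not* emulate: free-swimming dynamics (speed
is prescribed, not emergent), a persistent shed wake, out-of-plane
flow, and measurement artefacts other than additive Gaussian velocity
noise. Consequently, passing pipeline tests on the swimmer
demonstrate internal consistency and the *directional* contrast
between gaits (pull share of thrust and efficiency higher for the
traveling wave), not quantitative agreement with any animal; solver
accuracy is claimed only on the analytic cases.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `rho`, `mu` | 998, 1.0e-3 | kg/m³, Pa·s | fresh water at 25 °C; config-overridable |
| `min_valid_paths` | 3 | – | rays required before a node is trusted |
| `surface_sample_offset` | 2 | cells | outward pressure sampling distance |
| `n_control_points` | 60 | – | contour resampling |
| `dead_band` | 0 | Pa | pull/push threshold is exactly ambient |
| `gamma0` | 0.025 | m²/s | blob circulation scale (no-slip calibration) |
| `kappa` | 2 | – | dipole strength (no-slip calibration) |
| `tau_lag` | `T_p/12` | s | vorticity-formation lag |
| `seed` | 0 | – | governs all stochastic elements |

## Problem sizes and determinism

The shipped tests and the acceptance script use: Taylor–Green at
$32^2$–$128^2$ with 5 frames; a $161^2$ cylinder window (16 radii
across); swimmer runs on a 0.47 m × 0.14 m raceway window at 2 mm
node spacing, 30 frames at 24 frames per undulation period, averaged
over the last full cycle. Everything is deterministic under a fixed
seed: the only random elements are the measurement-noise draws, which
run in a private RNG stream that restores the caller's state.

## Known limitations

* The planar momentum balance ignores out-of-plane transport; a 2-D
  slice of a genuinely 3-D flow inherits that bias, as any planar
  pressure-from-PIV method does.
* Viscous *surface* (shear) forces are not computed — the
  decomposition covers pressure forces only, and reports say so.
* Blocked rays are discarded rather than routed around the body, so
  nodes in deep mask shadows rely on the interpolation fill (flagged,
  and counted in QC).
* With ambient-zero edges the solver assumes the window boundary is
  far field; windows clipping energetic flow need the `boundary`
  argument or a larger field of view.
* Under velocity noise the convective term leaves an error floor of
  order $\rho\,u\,u'$ that the ray median cannot remove; for steady
  flows, averaging the per-frame pressure estimates suppresses it
  (the robustness study reports the three-frame average).
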