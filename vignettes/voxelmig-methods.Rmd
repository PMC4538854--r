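---
title: "voxelmig: model and numerical methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{voxelmig: model and numerical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`voxelmig` simulates a single cell migrating through a three-dimensional
extracellular matrix (ECM) on a regular lattice of 3 um cubic voxels. Each
voxel is matrix, pore space, or part of the cell (cortex, cytoplasm or
nucleus). Two coupled ingredients drive migration:

**Mechanosensing.** Per axis, each cell voxel is a passive spring
(`Kpas` = 1 kPa) in parallel with an actin spring (`Kact` = 10 kPa) in
series with an acto-myosin actuator. The stress a voxel transmits to its
surroundings is a continuous piecewise function of its axial strain
$\varepsilon$: purely passive below $\varepsilon_{min} = -0.4$ and above
$\varepsilon_{max} = 0.4$, rising through an actuator branch to a peak of
$\sigma_{max}/K_{act}$, with $\sigma_{max}$ = 2.5 kPa in the cortex (the
one-voxel surface shell) and 1.5 kPa in the cytoplasm. The nucleus — a
rigid 9 um ball of voxels that tracks the cell centroid and is never added
or removed — is purely passive. Mechanical equilibrium is solved with one
trilinear hexahedral finite element per voxel (ECM linear elastic,
$\nu = 0.3$; cell material $\nu = 0$ so the axes act independently), the
actuator stress entering as an element eigenstress. Because the actuator
stress depends on the strain that it itself produces, equilibrium is a
fixed point: solve, re-evaluate the stress law at the new strains, repeat.
Contraction is positive volumetric stress
$\sigma_v = (\sigma_x + \sigma_y + \sigma_z)/3$, and matrix displacements
point toward the cell.

**Stochastic shape update.** Every step (dt = 5 min), candidate voxels at
the cell surface are added and surface voxels removed with probability

$$p_* = p^0_* + p^{max}_*\left(1 - e^{-k^0_*(\lambda^{\sigma}F^{\sigma} +
\lambda^{\Delta\sigma}F^{\Delta\sigma} + \lambda^{C}F^{C} +
\lambda^{F}F^{F})\,dt}\right)$$

with four stimulus factors in [0, 1]: stress magnitude
($\sigma_v/\sigma_{max}$ weighted by the cosine of the angle to the
maximum-stress direction $d_{\Delta\sigma}$), stress direction (pure
alignment), chemical (adjacent-voxel concentration difference), and flow
(alignment with the local flow direction). $d_{\Delta\sigma}$ joins the
cell centroid to the voxel of maximal $\sigma_v$ — polarization emerges
from the morphology rather than being imposed. Additions use the angle
between the candidate offset and the reference direction; removals use the
angle between the centroid-to-voxel direction and the same reference, with
the complementary ($|\sin|$, beyond 90 degrees) branch, so the cell
extends where it pulls hardest and retracts at its rear and flanks.

## Design choices where the formulation was open

* **Event drawing.** One addition trial per candidate matrix voxel (its
  probability read from the most stressed adjacent surface voxel) and one
  removal trial per non-nucleus surface voxel, from a frozen snapshot of
  the shape, with additions winning conflicts. Drawing one addition trial
  per (surface voxel, neighbour) *pair* instead makes expected additions
  exceed removals at every morphology and the cell grows without bound —
  we verified this directly; the per-candidate rule is the nearby variant
  that keeps the cell bounded.
* **Connectivity.** Stochastic removal can disconnect the shape. After
  each step only the 6-connected component containing the nucleus is
  kept; orphaned voxels revert to matrix. Rare large fragmentation events
  can strip a replicate to its nucleus; such replicates keep their
  trajectory up to that step and are flagged (`attr(log, "truncated")`).
* **Chemotactic normalization.** The concentration difference between two
  adjacent 3 um voxels is a factor ~1e-2 to 1e-3 of the domain-scale
  concentration, so normalizing by the maximum *concentration* makes the
  chemical factor numerically inert — irreconcilable with the strong
  chemotactic steering the model family is meant to show. The default
  reference is therefore the maximum adjacent-voxel concentration
  *difference* over the domain, which maps a uniform gradient to factors
  spanning [0, 1] exactly like the two alignment factors
  (`chemNorm = "cmax"` restores the literal normalization).
* **Gradient orientation.** In migration scenarios the concentration
  increases along +x, so the chemotactic drive, the flow direction and
  "the applied gradient direction" coincide.
* **Nucleus.** Diameter (9 um), rigidity and the re-snap rule are
  modelling choices: the nucleus is passive and its dynamics are otherwise
  unspecified.

## Numerics

* **Moving window.** Displacements decay like $1/r^2$ from the cell and
  $\sigma_v$ saturates with confinement stiffness, so equilibrium is
  solved on the cell bounding box padded by a configurable margin
  (scenarios use 4 voxels, built with 2 voxels of hysteresis slack),
  with fixed displacements on the window boundary. Widening the margin
  from 5 to 19 voxels moves the cortex-mean $\sigma_v$ of the reference
  sphere by under 1%.
* **Solver.** Jacobi-scaled SSOR-preconditioned conjugate gradients via
  Eisenstat's trick, warm-started across fixed-point iterations and steps;
  the assembled pattern is cached while the window stands still.
* **Fixed point.** The actuator update is damped per component by
  $(K_{pas}+k)/(K_{pas}+k+s')$, where $s'$ is the analytic branch slope
  and $k$ a secant estimate of the local confinement stiffness
  (initialized from the neighbouring moduli). Where the softening branch
  is steeper than the local confinement no damped iteration can converge
  (a genuine snap-through); those voxels move toward the nearest stable
  root of their local series problem, solved by bisection. Scenario runs
  iterate to 0.03 kPa on $\sigma_v$ (a probability perturbation below
  1e-4); reported single solves use 1e-3 kPa.
* **Single-voxel closed form.** The independent reference solution places
  the mechanosensing element in series with a confinement spring
  $5.26\,E/(1+\nu)$ — the stiffness of a cubic cavity in a large
  trilinear-element lattice under uniform per-axis contraction, measured
  once on meshes of 17 to 33 voxels per side (it is mesh-size independent
  to three digits, and about 2.6 times the continuum spherical-cavity
  value $2E/(1+\nu)$). The full solver tracks this curve to better than
  0.1% across E = 0.1 to 1000 kPa.
* **Porous matrix.** The generator builds the strut network of a
  Poisson-Voronoi tessellation (seed spacing = target pore size; the
  best-ranked voxels by closeness to three-cell junctions become solid, at
  exactly the target solid fraction). Carving independent 20 um spherical
  voids at porosity 0.9 was tried first and rejected: on a 3 um lattice
  the septa between voids fall below one voxel and the solid phase
  disintegrates into floating debris. Boundary-disconnected fragments are
  relabelled as pore space (they carry no load); in the mechanics, pore
  voxels get a background stiffness of 1e-2 of the solid modulus, which
  suppresses rigid-body modes and keeps the conjugate-gradient iteration
  well conditioned while adding a confinement that is negligible against
  `Kpas`.
* **Skipped solves.** When both stress factors are disabled (flow- or
  chemistry-only scenarios) the mechanical solution cannot influence the
  trajectory — it enters the dynamics only through those factors — so the
  solve is skipped and stress outputs are recorded as NA. The trajectory
  distribution is unchanged exactly.
* **Transport.** The box-domain environment is the reported gel condition:
  a linear concentration profile and uniform flow. The finite-volume
  Darcy and upwind advection-diffusion solvers are provided for
  consistency studies (exact for homogeneous permeability; within 2% of
  the 1-D advection-diffusion closed form at 100 cells). The default
  viscosity is water's 1e-3 Pa s: the printed 1e3 Pa s is inconsistent
  with the reported ~3 um/s interstitial speeds by six orders of
  magnitude and is treated as a typo (it remains selectable).

## What the generator emulates — and what passing tests do not show

Scenario runs place an initially spherical 30 um cell at the centre of a
box-like gel domain (300 x 300 x 120 um, or the reduced 150 x 150 x 90 um
"desk scale" used throughout the tests and the acceptance script — the
dynamics depend on the probability law, not the domain size, as long as
the boundary stays several voxels away from the cell) and run 100 steps
of 5 min with the published parameter set. Replicates differ only by
seed; a fixed seed reproduces a run bit for bit.

Synthetic environments are idealized: uniform flow and exactly linear
gradients, isotropic linear-elastic matrix, no fibre architecture, no
hindrance or drag in dense matrices, no autocrine signalling, no
fluid-structure coupling. Passing tests therefore show that the
implementation reproduces the *model's* behaviour under its published
parameters, not that the model predicts any particular real cell type.

Two quantitative caveats deserve emphasis, both analysed during
development and revisited in the package's acceptance report. First, with
the published sensitivity constants the mechanical and flow terms in the
probability exponent are at most ~1e-2, so those stimuli modulate the
baseline probabilities by under 2%; the directional statistics they
produce (slight forward bias, ~40-50% backward turns) are consistent with
the published directionality for single-factor cases, but the published
absolute speed scale (~0.4 um/min mean speed, implying ~2 um centroid
steps for a ~500-voxel cell) is not reachable from a baseline turnover of
p0 = 0.1 under any event-drawing rule we examined — the simulated mean
speeds land near 0.1 um/min while the effective speeds (net displacement
over time) match well. Second, the cortex-mean volumetric stress of the
reference sphere computes to ~1.37 kPa against the reported ~1.2 kPa; the
published finite-element formulation is not described in enough detail to
close the gap, and no parameter was adjusted to force agreement.

## Problem sizes used by the packaged checks

Unit and property tests run on lattices of 10-50 voxels per side. The
acceptance tests use 2 replicates per scenario and the acceptance script
3, both on the desk-scale domain at 100 steps; the porous scenario uses
the same 3 replicates. These sizes are the package's reporting choice;
all of them can be raised through `scenarioSpec()`.
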