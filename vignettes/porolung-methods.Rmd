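---
title: "Methods: poroelastic simulation of breathing-induced lung deformation"
author: "porolung"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: poroelastic simulation of breathing-induced lung deformation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

porolung treats lung parenchyma as a porous elastic medium: a soft tissue
skeleton whose pores are filled with air. Airflow and deformation are
coupled in both directions — air filtering through the tissue pressurizes
and deforms it, and the deforming skeleton stores and releases pore air.

Two fields live on the same tetrahedral mesh.

**Pore pressure** $p(\mathbf{x},t)$ obeys a Richards-type balance of
compressible storage, Darcy flux and skeleton dilatation,

$$\phi\beta\,\frac{\partial p}{\partial t}
  = \nabla\cdot\!\left[\frac{k}{\mu}\left(\nabla p + \rho \mathbf{g}\right)\right]
  - \frac{\partial}{\partial t}\left(\nabla\cdot\mathbf{u}\right),$$

with porosity $\phi$, air compressibility $\beta$, permeability $k$, air
viscosity $\mu$ and air density $\rho$. The dilatation-rate term is the
two-way coupling: because the skeleton compliance dwarfs the air
compressibility here (by a factor of roughly 500 at the default material
values), this term — not $\phi\beta$ — provides almost all of the effective
storage, and the pressure dynamics are consolidation dynamics.

**Displacement** $\mathbf{u}(\mathbf{x},t)$ obeys a quasi-static
poroelastic Navier equation,

$$G\nabla^2\mathbf{u} + \frac{G}{1-2\nu}\nabla(\nabla\cdot\mathbf{u})
  = \nabla p - \mathbf{f},$$

equivalently the classical Navier–Cauchy operator with Lamé parameter
$\lambda = 2G\nu/(1-2\nu)$. Orthotropic anisotropy enters exactly where the
model declares it: the shear modulus may take distinct values
$G_{xy}, G_{yz}, G_{xz}$ in the three coordinate planes, each obtained from
a Young's-modulus field through $G = E/[2(1+\nu)]$; the volumetric term
uses the element-mean $G$ with a single Poisson ratio $\nu$. The
incompressible limit $\nu = 0.5$ is rejected everywhere since the
$1/(1-2\nu)$ factor diverges.

### Boundary conditions and the pressure-load formulation

The inlet patch (trachea side) carries a Dirichlet pore pressure equal to
the phasic drive; the rest of the surface is a zero-flux Darcy boundary.
Displacement is fixed on a small patch around the inlet (anchoring the
hilum and removing rigid-body modes) and unconstrained elsewhere.

The pressure load $\nabla p$ is applied in its integrated-by-parts weak
form $\int_\Omega p\,\nabla\cdot\mathbf{v}\,d\Omega$, which makes the
natural condition on the unconstrained surface zero **total** traction:
the pore air pushes on the skeleton at the free surface, as in the
standard total-stress formulation of porous-media mechanics. This choice
is not cosmetic. Applying the point-wise $-\nabla p$ quadrature instead
(which would make the natural condition zero *effective* traction) leaves
the boundary working term $\oint p\,\dot{\mathbf{u}}\cdot\mathbf{n}\,dS$
uncompensated; the discrete flow/elasticity coupling blocks are then not
adjoint, the semi-discrete system is not dissipative, and on a free body
the time stepping amplifies by a large factor per step — we measured
catastrophic growth within a fraction of a breathing cycle. With the
adjoint pairing (the elastic coupling block is exactly the transpose of
the dilatation block) backward Euler is unconditionally dissipative. One
consequence worth knowing: a *uniform* pore pressure inflates the phantom
(balloon mode) rather than producing zero displacement; its net force
still vanishes identically, which the test suite asserts.

## Discretization and coupling

Both fields use linear tetrahedra (P1) on the same mesh. The flow storage
is mass-lumped; Darcy conductivity $k/\mu$, the dilatation coupling and the
elastic stiffness are assembled element-wise with exact one-point
quadrature (all integrands are element-wise constant for P1). Time
integration is first-order implicit (backward Euler), dt = 0.02 s by
default — 200 steps per 4 s breathing cycle; runs reject dt > period/20 as
under-resolving the drive.

Each implicit step is linear with a constant matrix, so the default
coupling scheme is **monolithic**: the $4N \times 4N$ block system
(pressure + three displacement components) is factorized once per run by
sparse LU and each step costs one forward/back solve plus one round of
iterative refinement; the relative residual is verified against
`linear_solver_tol` (default 1e-8) and the run aborts with diagnostics if
it is exceeded. A **staggered** alternative (`solver_config(coupling =
"staggered")`) iterates flow and elasticity solves with fixed-stress
stabilization — an added storage term $1/K_{dr}$ per element that cancels
identically at convergence — and under-relaxation (default 0.7, cap 50
iterations, warning and step acceptance on non-convergence). With the
adjoint coupling blocks the staggered loop converges in roughly 10–20
iterations at tolerance 1e-6 and agrees with the monolithic path to
~1e-7 relative; the monolithic path is the default because it is exact per
step and slightly faster at the default step size.

Kinematics are small-strain and total-Lagrangian: the mesh is never
re-deformed, so the response is exactly linear in the drive amplitude
(asserted to 1e-8 in the tests). Reported displacements scale linearly
with the inlet amplitude; for very soft heterogeneous fields the linear
model happily produces displacements beyond small-strain validity, which
is intentional — phase lags, stabilization indices and peak *ratios* are
amplitude-independent, and those are the quantities of interest.

## The multizone phantom

The phantom is an ellipsoid (default semi-axes 0.06 × 0.08 × 0.12 m,
human-lung scale) partitioned into concentric scaled-ellipsoidal shells
(default three, at radial fractions 0.4 / 0.7 / 1.0) standing in for the
core-to-periphery organisation of the airway tree. The mesh is a graded
radial extrusion of a subdivided-octahedron sphere triangulation: every
zone interface is an exact node shell, layers between shells are prisms
split into three tetrahedra by the smallest-global-vertex diagonal rule
(conforming across neighbours by construction), and the innermost shell
closes onto the centre node. Two properties motivated this construction
over a deformed-cube grid: no tetrahedron has all four nodes on the outer
surface (such "cap" elements have circumradius pinned at the surface
curvature radius regardless of resolution), and the radial node density
follows the per-shell target edge lengths so the core is genuinely refined
— tangential element size additionally shrinks in proportion to radius.
Tetrahedron orientation is normalized to positive signed volume, and the
validator checks watertightness (every interior face shared by exactly two
tetrahedra), contiguous zone labels, and boundary-tag consistency.

The inlet patch is the set of surface nodes within `inlet_radius`
(default 0.01 m) of the superior-medial pole, never smaller than the
nearest node plus its one-ring so the Dirichlet orifice is resolved at any
mesh resolution; the anchoring patch is the surrounding annulus within
`fixed_radius` (default 0.025 m). Construction is fully deterministic;
the seed argument is recorded with the mesh and fixes any randomized
meshing step (the current scheme has none). Meshes round-trip through
legacy ASCII VTK and Gmsh 2.2 files at full double precision.

## Material parameters

| parameter | default | units | rationale |
|---|---|---|---|
| Poisson ratio $\nu$ | 0.4 | — | reference tissue value within the 0.25–0.47 range used for lung |
| tissue density | 700 | kg/m³ | reference lung density |
| Young's modulus (linear case) | 178 | Pa | lung-wide mean stiffness |
| stiffness range (anisotropic) | 10–500 | Pa | parenchyma to rigid structures (tumor, large-airway wall) |
| porosity $\phi$ | 0.5 | — | standard air-fraction assumption, configurable |
| air density / viscosity / compressibility | 1.2 / 1.8e-5 / 1/101325 | SI | standard air at ambient conditions |
| branch radii (3 zones) | 0.04 / 0.02 / 0.01 | m | normalized radii halving outward, zone permeability ratio 16:4:1 via $k=\phi R^2/8$ |
| permeability factor | 0.0316 | — | geometric midpoint of the studied 0.01–0.1 normalized range |
| inlet amplitude / period | 300 Pa / 4 s | — | spirometry-scale phasic drive |

The branch radii are parameters of the porous-continuum parameterization,
not anatomical calibres. Together with the permeability factor they set
the *consolidation time* $\tau \sim \mu L^2 S_\mathrm{eff}/k$ of the
tissue (effective storage $S_\mathrm{eff} \approx 1/(\lambda+2G)$), which
is the single quantity that controls hysteresis: the defaults place the
homogeneous 178 Pa tissue at $\tau$ of a few milliseconds — quasi-static
against the 4 s cycle, so the linear case tracks the drive in phase and
peaks at mid-cycle — while regions near the 10 Pa soft bound are ~18×
slower and develop peak lags of several hundredths to tenths of a second.
This timescale calibration is part of the phantom's definition and was
fixed from the 1-D phasor analysis plus one verification pass on the
default phantom, before the verification bounds were frozen. Because the
quasi-static regime is flat, landmark peak displacements move by under a
percent across the whole 0.01–0.1 permeability range (asserted at 2 % in
the tests) — the model's permeability insensitivity.

## The synthetic elasticity generator

The generator stands in for a subject-specific, image-derived stiffness
map; it does not estimate elasticity from images. Seeded white noise on
elements is smoothed by iterated face-neighbour averaging (iteration count
$\approx (\ell/h)^2$ for correlation length $\ell$ and mean element size
$h$), then affinely rescaled and clipped to [`ym_min`, `ym_max`] with the
affine location solved by root finding so the element-volume-weighted mean
matches `ym_mean` to numerical precision. Clipping is deliberate: it
leaves coherent regions pinned at the bounds, mimicking soft parenchyma
abutting rigid structures, and those soft regions carry the compliance
storage that produces hysteresis. The default correlation length of
0.08 m gives lobe-scale coherent regions; small-scale heterogeneity
(e.g. 0.02 m) produces patches whose consolidation time — which scales
with the squared region size — barely differs from the background, and
correspondingly little hysteresis. Orthotropy is applied as three
plane-wise multipliers (`axis_contrast`, default 1.25 / 1.0 / 0.8) on the
scalar field before conversion to shear moduli; an optional spherical
inclusion is pinned at `ym_max` (rigid tumor). Identical spec and seed
reproduce the field exactly.

What passing tests show — and do not show — about real lungs: the
generator reproduces controlled *statistics* (range, volume-weighted
mean, smoothness) on a convex phantom, so the tests demonstrate that
heterogeneous anisotropic stiffness produces hysteresis, cycle-to-cycle
loop non-closure and amplified motion under identical drive. They do not
validate against patient anatomy: a real lung's lobar geometry, pleural
constraints, airway-wall structure and image-derived stiffness spatial
pattern are all outside the phantom, and patient-reported numbers
(specific lag values, TDE against 4DCT landmarks) are not reproducible
here.

## Kinematics analysis

* **Hysteresis lag** — within-cycle peak time of |component| (or the
  magnitude), refined by a local quadratic fit through the three samples
  around the discrete peak, minus the mid-cycle drive peak; ties break
  toward the earliest peak; flat traces return `NA`. A cross-correlation
  lag (shift maximizing correlation with the drive over a resampled
  uniform grid) is reported alongside as a robustness check. Lag checks
  are restricted to components carrying at least 10 % of the run's
  largest component peak: near-zero components have noise-level peak
  times and no meaningful phase.
* **Cycle stability** — smallest cycle whose peak all later cycles match
  within a relative tolerance (default 5 %).
* **Loop gap** — consecutive-cycle 3-D trajectories resampled at 200
  matched phases; the maximum point-wise distance measures loop
  non-closure.
* **Super-cycle period** — autocorrelation of the per-cycle peak sequence;
  the dominant lag is reported as a period when its normalized
  autocorrelation exceeds 0.3, requiring at least 8 cycles.
* **TDE** — mean and max Euclidean distance between predicted and
  reference landmark displacement vectors at a breathing phase; symmetric
  and landmark-wise triangle-inequality-consistent.

Default landmarks mirror the classic monitoring points: the apex (top
surface), a lateral mid-height node (rib-cage side) and a medial
mid-height node, all chosen outside the displacement-fixed patches. The
end-of-cycle displacement of the linear case is asserted below 5 % of the
cycle peak ("nearly negligible").

## Verification

The suite is built on independent oracles at small problem sizes:

* **1-D consolidation** (Terzaghi-type closed-form series, implemented
  independently in the tests): a laterally confined 16×2×2-cell column,
  driven by a constant boundary pressure, matches the series solution to
  better than 2 % RMS of the drive at three times, converges under
  space–time refinement, and reaches the closed-form fully consolidated
  tip displacement $-PL/(\lambda+2G)$.
* **FEM patch test**: prescribed linear displacement on the boundary of a
  homogeneous box reproduces the linear field at interior nodes to
  machine precision; a pure xy shear energy scales exactly with $G_{xy}$
  and is exactly independent of $G_{yz}, G_{xz}$.
* **Steady Darcy bar**: Dirichlet pressures at both ends give the exact
  linear profile.
* **Exact nullities**: zero drive gives exactly zero states; uniform
  pressure gives exactly zero net force; a uniform pressure lies exactly
  in the Darcy operator's kernel.
* **Refinement**: halving the target edge lengths multiplies the element
  count by 4–16 and halves the maximum circumscribed-sphere radius
  (independent circumradius checker in the tests); landmark peaks move
  < 1 % under dt halving and < 10 % between the ~5000- and ~8000-element
  phantoms.

End-to-end checks run on the ~5000-tetrahedron coarse phantom with
dt = 0.02 s over 3 cycles (6 for stabilization); these sizes keep the
whole suite within a few minutes while leaving the verified quantities
(peak timing to ±dt, generator statistics to 1 %) well resolved.

## Known limitations

* Small-strain, fixed-mesh kinematics: no geometric nonlinearity, no
  contact with the rib cage, no pleural cavity mechanics.
* The airway tree is a continuum: no airway-resolving CFD, no turbulence,
  and the inlet is a surface patch rather than a modelled trachea.
* Equal-order P1–P1 interpolation is adequate in the studied permeability
  regime but is not the right element pair for strongly undrained
  problems (spurious pressure modes would appear at much lower
  permeability-storage products).
* The synthetic stiffness field is a statistical surrogate; nothing in it
  is subject-specific, and cardiac-motion coupling is out of scope.
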