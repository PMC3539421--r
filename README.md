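# porolung

Finite-element simulation of airflow-driven lung deformation on multizone
poroelastic phantoms, with breathing-cycle hysteresis analysis.

## The problem

During breathing, lung tissue deforms continuously, and with it any tumor a
radiotherapy beam is trying to track. Modelling that motion from first
principles requires coupling the airflow inside the lung to the mechanics of
the parenchyma. Resolving the branching airway tree explicitly is
computationally prohibitive, so this package takes the porous-continuum
route: the parenchyma is a porous elastic medium through which air filters,
organised as a *multizone* structure — concentric shells whose permeability
falls from the core (large branches) to the periphery (tip branches)
following `k = φR²/8` for a per-zone normalized branch radius `R` and
porosity `φ`.

Two fields are solved together on a tetrahedral phantom:

* **Pore pressure** `p` — a Richards-type equation combining compressible
  storage, Darcy flux, and the skeleton dilatation rate:

  `φβ ∂p/∂t = ∇·[(k/μ)(∇p + ρg)] − ∂(∇·u)/∂t`

* **Displacement** `u` — a quasi-static poroelastic Navier equation whose
  shear modulus `G = E/[2(1+ν)]` may vary spatially and by coordinate plane
  (orthotropic anisotropy in the xy, yz and xz planes):

  `G ∇²u + G/(1−2ν) ∇(∇·u) = ∇p − f`

A phasic inlet gauge pressure (`sin²`, period 4 s) drives breathing cycles.
The central scientific comparison is **linear-isotropic versus spatially
varying anisotropic elasticity**: with a homogeneous mean-stiffness field
(178 Pa) the motion follows the drive in phase, peaking at mid-cycle; with a
heterogeneous orthotropic field spanning 10–500 Pa, soft regions consolidate
slowly and the motion develops *hysteresis* — peak-time lags of tenths of a
second, distorted trajectories, and breathing loops that no longer close.
The package quantifies this with per-landmark lag times, a cycle-stability
index, trajectory loop-closure gaps, super-cycle periodicity detection, and
the target-deformation-error (TDE) metric.

Who this is for: researchers prototyping deformable lung models for
tumor-motion estimation, and anyone needing a self-contained, verifiable
poroelastic FSI testbed with controlled synthetic material fields.

## Worked example

```r
library(porolung)

cfg <- default_config(output_dir = "demo-out", seed = 1L)
out <- run_comparison(cfg)   # ~20 s: two 3-cycle runs on a ~5000-tet phantom
print(out)
```

which prints (landmarks: A apex, B lateral mid-height, C medial mid-height;
peaks in metres, lags in seconds):

```
Linear (isotropic) vs anisotropic elasticity comparison
 landmark component  peak_iso peak_aniso peak_ratio   lag_iso lag_aniso
        A         x 0.0002780    0.02702     97.198  0.006896   0.02401
        A         y 0.0101244    0.07003      6.917  0.005336   0.02679
        A         z 0.0122897    0.16148     13.139  0.006455   0.03305
        B         x 0.0009518    0.90208    947.736  0.005054   0.03389
        B         y 0.0582223    0.25437      4.369  0.006461   0.02885
        B         z 0.0146310    0.01838      1.256  0.014355   0.15141
        C         x 0.0001967    0.17540    891.551  0.009122   0.03165
        C         y 0.0043813    0.15269     34.849 -0.027697   0.07462
        C         z 0.0398452    0.25457      6.389  0.006082   0.03264
Checks:
   iso_lag_within_step : PASS
   aniso_lag_exceeds_2steps : PASS
   aniso_loop_gap_larger : PASS
```

Reading it: every amplitude-carrying component of the linear run peaks
within one time step (0.02 s) of the mid-cycle drive peak at t = 2 s,
while the anisotropic run lags the drive by up to 0.15 s and its peaks are
several times larger — the hysteresis signature of heterogeneous tissue.
CSV reports (per-cycle lags, loop gaps, stabilization cycles), each headed
by the seed and configuration hash, land in `demo-out/`.

Lower-level building blocks:

```r
mesh <- build_multizone_phantom(coarse_phantom_spec(), seed = 1)  # zoned tet mesh
mat  <- generate_elasticity_field(mesh, elasticity_field_spec(seed = 1))
res  <- run_simulation(mesh, mat, waveform(), solver_config(n_cycles = 3))
hysteresis_report(res)              # lags, loop gaps, stabilization
export_mesh(mesh, "phantom.vtk")    # legacy VTK (or .msh for Gmsh 2.2)
export_vtk_series(res, "frames")    # time series for ParaView
```

A thin command-line interface (`inst/exec/porolung`) exposes the same
pipeline as subcommands `phantom`, `simulate`, `compare`, `analyze`,
`validate`, configured by YAML (see `inst/extdata/demo-config.yaml`).

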