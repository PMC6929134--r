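---
title: "The coarse-grained magnetopolymersome model in mpsdyn"
author: "mpsdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The coarse-grained magnetopolymersome model in mpsdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The system

A magnetosensitive polymersome (MPS) is a submicron vesicle whose
amphiphilic double-layer membrane confines a monolayer of magnetic
nanoparticles (MNPs) between its two polymer leaflets.  Under a uniform
magnetic field the nanoparticles chain up, the capsule stretches along the
field, and its inner cavity -- the drug-carrying compartment -- shrinks
slightly.  `mpsdyn` implements a coarse-grained Langevin-dynamics model of
this object and measures the size dependence of the field response.

The model has three ingredients:

* **Two nested triangulated elastic shells.**  Each shell is a quasi-2D
  triangular mesh of polymer beads (icosahedral subdivision projected onto
  a sphere).  The mesh nodes are connected by harmonic edge springs
  (`k_stretch`), each triangle carries an area-restoring energy
  (`k_area`), and each mesh edge carries a dihedral angle spring
  (`k_bend`) whose reference angle is recorded from the built geometry.
  A fraction `cb` of the shell nodes is tied to the subtending node of the
  other shell by a linear spring of stress-free length `h`, the intershell
  distance, which serves as the length unit.
* **Dipolar nanoparticles.**  Each MNP is a soft sphere of diameter
  `dp = 0.3 h` carrying a point dipole of fixed magnitude at its centre.
  Pairs interact through the full anisotropic dipole--dipole potential
  (all pairs, open boundaries) plus Weeks--Chandler--Andersen (WCA)
  repulsion; MNPs also repel the shell beads sterically, which confines
  them to the gap `hgap = 0.35 h` -- wide enough for exactly one layer.
* **An implicit solvent.**  Every particle follows underdamped Langevin
  dynamics: conservative forces, linear friction, and Gaussian noise obeying
  the fluctuation--dissipation relation, so the stationary ensemble is
  Boltzmann at `kBT`.  MNP orientations follow the rotational counterpart
  driven by dipolar and Zeeman torques.

Two dimensionless groups control the magnetism: the dipolar coupling
constant `lambda = mu0 mu^2 / (dp^3 kBT)` (contact pair energy over thermal
energy) and the Langevin field parameter `xi = mu0 mu H0 / kBT` (Zeeman
energy over thermal energy).  For 15 nm ferrite particles
(`M = 500 emu/cm^3`) at room temperature, `lambda ~ 5`; fields of a few
hundred Oe reach `xi ~ 10`.  The conversion helpers
(`moment_from_material()`, `lambda_from_material()`, `xi_from_field()`)
evaluate these formulas in Gaussian units.  Two precision caveats worth
recording:

* Ferrite moments are usually quoted to one figure.  With the exact
  moment `mu = (pi/6) M dp^3 = 8.8e-16 emu` the coupling constant
  evaluates to 5.6; with the commonly quoted `8e-16 emu` it evaluates to
  4.6, i.e. `lambda ~ 5`.  `lambda_from_material()` accepts either (the
  `mu_emu` argument propagates a quoted moment).
* Direct evaluation of the field conversion gives `xi ~ 39` for
  `H0 = 2 kOe` with this moment -- so `xi = 10` corresponds to roughly
  0.5 kOe, not to the 2 kOe sometimes associated with it; the package
  reports the formula value.

## Geometry and construction

The capsule diameter is `D = q h`, referred to the outer-shell bead
mid-surface, so the built outer shell has radius `q/2` and the inner shell
radius `q/2 - 1`.  The basic-state cavity (polyhedron spanned by the
inner-shell bead centres) is then close to a sphere of diameter `D - 2h`,
the natural reference for the volume defect.  Bead diameters obey
`hgap = h - (din + dout)/2`; only the sum is physically constrained, and
`din = dout = 0.65 h` is used, which makes the beads large against the
MNPs.  Both shells share one subdivision level (equal bead counts, as the
membrane sandwich demands), chosen as the coarsest level whose mean outer
edge does not exceed `mesh_coarsen * dout`.  Impenetrability of the wall
is a pore-size condition: an MNP fits through a triangle of edge `a` only
if the circumradius `a/sqrt(3)` exceeds the WCA contact distance
`(dout + dp)/2`; the `mesh_coarsen` cap enforces the safe side of this
inequality, and the default (`1`) keeps edges at or below the bead
diameter so neighbouring beads touch.

MNPs are seeded uniformly in the gap: the count follows from the volume
fraction `phi` of the accessible intershell space,
`N = round(phi V_gap / ((pi/6) dp^3))`, positions are drawn uniformly over
the spherical band available to particle centres and relaxed by
deterministic soft-core pushes until no overlap is deeper than 10% of
`dp`, and moments are drawn isotropically.  Replicas of an experiment
share the geometry and the MNP positions and differ only in the moment
orientations (and thermostat noise), which matches the replica protocol
of the study design.

## Why there is a bending term

The mesh as literally specified -- edge springs plus area springs, free
folding along triangle borders -- has zero bending modulus.  A closed
triangulated surface with `kappa = 0` at finite temperature sits deep in
the crumpled phase: in test runs the inner shell lost half its radius
within a few reduced time units, which contradicts the inflated spherical
basic state that defines `V0`.  The membrane schemes this model family is
built on (object-in-fluid red-blood-cell membranes) stabilise the shape
with a dihedral bending force, and `mpsdyn` does the same: one harmonic
angle spring per mesh edge, reference angles from the built sphere.  The
default `k_bend = 12 kBT/rad^2` corresponds to a bending modulus
`kappa ~ sqrt(3)/2 k_bend ~ 10 kBT`, a typical polymer-membrane value:
two orders of magnitude above the crumpling threshold, far below the
stretching and dipolar energy scales, and small enough that the shells
remain visibly floppy (folds and wrinkles survive in snapshots).

## Membrane stiffness: a fluid membrane on a fixed mesh

An amphiphilic bilayer is a two-dimensional fluid: it conserves its area
but has no static shear modulus.  A fixed-connectivity triangulated mesh
is not a fluid -- its edge springs generate a shear modulus
`~ sqrt(3)/4 k_stretch` -- and elongating a sphere into a spheroid at
constant total area is a pure shear deformation.  With stiff edge springs
the capsule therefore cannot elongate no matter how strong the magnetic
driving: the mesh, not the physics, pins the shape.  `mpsdyn` separates
the two roles explicitly:

* `k_area` (default `500 kBT/h^2`) enforces the physical constraint --
  local and hence total area conservation (drift well below 1% in
  production runs) -- and keeps the triangles from degenerating;
* `k_stretch` (default `10 kBT/h^2`) only regularises the mesh.  It is
  deliberately small so the artificial shear modulus is negligible
  against the area and bending terms, approximating membrane fluidity on
  a solid mesh; the steric size of the beads (WCA with the confined
  nanoparticles) independently keeps the wall closed.
* `k_bond = 50 kBT/h^2` for the intershell springs, soft enough that the
  layer thickness fluctuates visibly at `cb = 0.2`.

Edge lengths do fluctuate under this choice (sd `~ sqrt(kBT/k_stretch)`),
which is the price of shear compliance; the pore-impenetrability margin
quoted above is computed against those fluctuations.  Raising `k_stretch`
toward the near-inextensible regime (several hundred) suppresses the
field-induced elongation roughly as `1/k_stretch`; both constants are
exposed in the configuration, and the methods tests exercise the
mechanics at several values.

## Dynamics and numerics

* Integrator: BAOAB splitting.  Velocity-Verlet kicks and drifts around an
  exact Ornstein--Uhlenbeck step for the velocities and angular
  velocities; moment orientations advance by `e <- e + (omega x e) dt`
  with renormalisation (the moments are axially symmetric, so a full
  quaternion treatment adds nothing).
* Masses: all unit, MNP inertia `m dp^2/10`; friction `zeta_t = 1`,
  `zeta_r = zeta_t dp^2/3`.  Equilibrium observables do not depend on
  these; only relaxation rates do.
* Timestep `dt = 0.002` reduced time, validated by the NVE-limit energy
  conservation test; a run aborts if any particle moves more than
  `0.25 dp` in one step.
* Dipolar sums are exact over all pairs (the capsule is a finite,
  non-periodic object); WCA pairs (MNP--MNP and MNP--bead only; the
  printed force decomposition contains no bead--bead sterics) come from a
  Verlet list over a uniform cell grid, rebuilt when any displacement
  exceeds half the skin.
* Randomness is a counter-based stream (seed, segment) feeding a
  xoshiro256** generator with Box--Muller normals, so trajectories are
  exactly reproducible for a given seed and independent across replicas.
* Equilibration follows the stated criterion -- stabilisation of the
  overall energy: windowed means of the total energy are compared between
  consecutive windows until the relative change drops below
  `equil_tolerance` (default `1e-3`), with a step cap that flags
  non-convergence as a warning rather than an error.

## Observables

* **Shape**: eigenvalues of the gyration tensor of the outer-shell beads;
  the field-aligned semi-axis `b` and transverse pair `a, c` give the
  elongation `epsilon = 2b/(a + c) - 1` (0 for a sphere).  Gyration
  moments are robust to single-bead outliers, and only ratios enter
  `epsilon`, so the surface-vs-solid eigenvalue scaling cancels for
  affine deformations.
* **Cavity volume**: signed-tetrahedra sum over the inner-shell
  triangulation (divergence theorem), with an orientation-repair pass for
  inconsistently wound input meshes; the volume defect is
  `(V - V0)/V0` with `V0` the same replica's basic-state volume.
* **Magnetization**: mean moment projection on the field axis.
* **Chain structure**: two MNPs are linked when closer than `1.3 dp` AND
  their dipolar pair energy is below `-1 kBT` (standard dipolar-cluster
  criteria, both exposed); chains are connected components.  The polar
  occupancy is the fraction of MNPs inside polar caps of half-angle 30
  degrees about the field axis -- the natural cap choice, sitting inside
  the complement of the pair-repulsion window (90 +- 35 degrees about the
  field).

## Protocol and problem sizes

`run_field_experiment()` implements the full study protocol per replica:
build, equilibrate at `xi = 0` (windowed stabilisation of the total
energy), measure the basic state, switch the field on instantaneously,
re-equilibrate, measure again.  Replicas differ only in the initial
moment orientations; summaries report replica means with standard
errors.

The shape response is a slow collective creep.  At the default friction
(`zeta_t = 1`) the `q = 6` elongation needs ~2.5e5 steps to reach its
stationary value; lowering the friction to `zeta_t = 0.3` -- purely a
sampling choice, since stationary averages do not depend on the friction
-- compresses this to ~5e4 steps (creep complete by ~100 reduced time
units, basic-state thermalisation by ~15).  The acceptance script runs
the `q = 6` experiment at full mesh resolution (642 beads per shell,
~210 nanoparticles) with 6 replicas and equilibration windows sized from
those relaxation times; the acceptance tests additionally run one
scaled-down `q = 14` replica (2562 beads per shell, ~1450 nanoparticles,
shortened field stage) for the size-ordering and polar-depletion
comparisons -- a converged multi-replica `q = 14` study needs hours per
replica on one core.  The README example uses a still smaller
configuration (`q = 5`, coarsened mesh, dilute filling) that runs in
about a minute.

## What the generator does and does not emulate

The synthetic capsule reproduces the study conditions: sizes `q = 6..14`,
`lambda = 5`, `phi = 0.11`, `cb = 0.2`, `dp/h = 0.3`, `hgap/h = 0.35`,
10 replicas differing in moment orientations.  It does not model
hydrodynamic interactions (implicit solvent only), membrane viscosity,
polydispersity of the MNPs, Neel relaxation (moments are rigid in the
particle body), or thermal undulations of a fluid (shear-free) membrane --
the mesh is a solid elastic network.  Passing tests therefore certify the
model's internal mechanics and statistical mechanics, not quantitative
agreement with any particular laboratory system.

## Known limitations

* The elongation magnitude depends on the membrane elastic constants,
  which the physical description leaves open; the defaults are a
  documented mechanical choice, not a fit.  At these defaults the
  `q = 6` capsule at `xi = 10` elongates to about 0.2, and the size
  dependence between `q = 6` and `q = 14` is weak at the run lengths the
  test budget allows: with a shear-compliant membrane both sizes
  approach a similar drive/elasticity balance, and both polar zones
  deplete almost completely.  A pronounced size effect may require the
  stiffer-membrane regime whose elastic constants the model description
  leaves unspecified, at the cost of a much smaller absolute response.
* Chain statistics at `xi = 0` can percolate into a single
  system-spanning cluster at `lambda = 5`, so the mean chain length is a
  blunt order parameter at zero field; the field-alignment of linked
  pairs is the sharper one.
* At strong coarsening the pore-size margin shrinks; `model_params()`
  refuses factors that would let MNPs slip through the wall.
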