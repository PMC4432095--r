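# molforge

A headless molecular building, symmetry and scalar-field toolkit for
computational chemistry, written as an R package with a thin command-line
front end.  It targets the scripting side of quantum-chemistry workflows:
building and editing molecular geometries without a GUI, preparing
multiconfigurational (RAS-type) active-space inputs, and turning volumetric
data (orbitals, densities, electrostatic potentials) into colored surface
meshes for visualization tools.

## What it does

* **Editing in ad-hoc internal coordinates.**  Geometry is stored in
  Cartesian coordinates but edited through transient internal coordinates
  defined by an ordered atom selection — a partial Z-matrix created on the
  fly: two atoms define a distance, three a valence angle, four a torsion.
  The first selected atom (or a rigid group containing it) moves; everything
  else stays bit-identical.  Dihedrals follow the IUPAC sign convention:
  the torsion A–B–C–D is positive when, sighting from B to C, the rotation
  carrying A onto D is counter-clockwise.
* **Symmetry operations as building tools.**  Inversion (1 pivot), rotation
  or translation (2 pivots) and reflection (3 pivots) replicate marked atoms
  into symmetry-equivalent positions; images landing within a merge
  threshold (default 0.3 Å) of an existing atom are merged in the average
  position.  The same machinery symmetrizes distorted structures (each atom
  is averaged with its symmetry image) and a decision-tree detector assigns
  Schoenflies point-group symbols (C1 … D6h, Td, Kh).
* **Scalar fields.**  Gaussian-cube I/O (bohr at the boundary, Å inside),
  grid arithmetic (spin/difference densities), densities from occupied
  orbitals (ρ = Σ nᵢψᵢ²), marching-tetrahedra isosurface extraction with
  signed orbital surface pairs, trilinear field sampling, and point-charge
  electrostatic potentials V(r) = Σ qᵢ/|r−rᵢ| (atomic units) evaluated in
  memory-bounded chunks.
* **Active-space bookkeeping.**  Orbital records (symmetry, energy,
  occupation) with filtering, σ/π classification by parity under reflection
  through the molecular plane, subspace assignment (frozen, inactive,
  RAS1–3, secondary, deleted) and export of RAS-style keyword blocks plus a
  per-orbital type-index string.
* **File formats and plug-ins.**  XYZ (multi-frame), a native `.mfx`
  dialect — a plain XYZ header followed by XML sections, so every XYZ file
  is a valid document and every document opens in any XYZ viewer — and an
  external converter plug-in registry keyed by filename extension.
* **Annotation and export.**  Arrows (automatic dipole-moment arrows),
  spheres, planes, triangles and parallelepipeds; ascii PLY scene export
  with per-vertex diverging colors symmetric about zero.

## Worked example: naphthalene from benzene

Delete the two hydrogens on one C–C edge of benzene, then rotate the
remainder 180° about that bare edge and merge duplicates:

```r
library(molforge)
b    <- make_molecule("benzene")                       # 12 atoms, D6h
m    <- delete_atoms(b, c(7, 8))                       # drop 2 H
op   <- make_operation(m, c(1, 2), "rotation", angle = 180)
naph <- apply_replicate(m, op, threshold = 0.3)
n_atoms(naph); mol_formula(naph)
#> [1] 18
#> [1] "C10H8"
detect_point_group(naph)
#> point group: D2h (7 elements listed, tol 0.1 A)
```

The same molecule results from inversion through a dummy atom at the bond
midpoint (`add_dummy(m, midpoint_of = c(1, 2))` and an `"inversion"`
operation): the two routes agree to ~2e-15 Å.  The equivalent edit script
for the command line (`exec/molforge build benzene.xyz naph.script out.xyz`)
is just:

```
delete 7 8        # one op per line, '#' comments
rotate 1 2 180
```

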