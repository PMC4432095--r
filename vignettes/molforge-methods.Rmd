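---
title: "Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molforge)
```

This vignette explains the models and numerical procedures behind
molforge, the parameters that matter, and the design choices made where
the design was genuinely open.  Units are angstrom and degrees
internally, everywhere; conversions (bohr in cube files, debye for
dipoles, atomic units for electrostatic potentials) happen only at
module boundaries.

## The data model

A molecule is an ordered list of atoms — element symbol, Cartesian
position, optional point charge — plus a bond set, optional trajectory
frames and free-form metadata.  Atom ids are 1-based row indices,
matching R indexing conventions; deletions compact the ids and report an
old-to-new map, so scripts can track atoms across edits.  The reserved
element symbol `"X"` denotes a dummy atom: massless, excluded from bond
perception and point-group detection, but a legal pivot for every
editing and symmetry operation.  This is what makes "rotate about the
midpoint of a bond" expressible: drop a dummy at the midpoint and use it
as the pivot.

Bonds are perceived by the standard distance criterion: atoms *i, j*
bond when |r⁠ᵢ − r⁠ⱼ| ≤ s·(Rᵢ + Rⱼ) with Cordero (2008) single-bond
covalent radii and scale s = 1.2.  The scale is a compromise: 1.1 misses
stretched bonds, 1.3 starts fusing next-nearest neighbours in dense
inorganic frameworks.  For Mn, Fe and Co the low-spin radii are used so
the table stays single-valued.  Bond perception here is display/grouping
plumbing, not chemistry: no bond orders, no aromaticity.

## Editing in ad-hoc internal coordinates

An ordered selection of 2–4 atoms defines a transient internal
coordinate (a partial Z-matrix entry created on the fly): distance,
valence angle at the middle atom, or torsion.  `set_internal()` moves
the *first* selected atom — or a rigid group containing it — by the
minimal transform that achieves the target:

* distance: translation along the line joining the two selected atoms;
* angle: rotation about the axis through the vertex normal to the
  selection plane (a right-hand rotation about BA×BC *decreases* the
  angle, so the applied angle is `current − target`);
* torsion: rotation about the B–C axis.  Numerically, a right-hand
  rotation of the A side about the B→C direction decreases the
  IUPAC-signed dihedral, which fixes the sign of the applied rotation.

Dihedrals are signed by the IUPAC convention, computed as
atan2((n₁×n₂)·û_BC, n₁·n₂) with n₁, n₂ the plane normals.  Angle targets
of exactly 0° or 180° are rejected rather than guessed: at 180° the
rotation plane is arbitrary, and silently picking one would make scripts
non-portable.  A fixed (non-mover) selected atom may sit inside the
mover group only when the transform leaves it in place — the common case
is the on-axis carbon when a whole CH₃ rotates about its own C–C bond —
and any group member that is a fixed reference *not* invariant under the
transform is an error.  Non-movers are never rewritten, not even with
their own values, so they stay bit-identical across edits.

Fragment attachment replaces a hydrogen: the fragment's declared link
atom is placed along the former heavy-atom→H direction at the sum of
covalent radii; the fragment's attachment axis (minus the mean of unit
bond vectors at the link atom — its "missing valence" direction) is
aligned to point back at the heavy atom; the residual roll is fixed by
putting the fragment's declared reference atom anti-periplanar to the
lowest-id heavy neighbour of the attachment atom.  Every choice here is
deterministic on purpose: the same script must always build the same
durene.

## Symmetry operations

Operations are affine isometries x ↦ Qx + t assembled from selected
pivots: inversion from one point, rotation (given angle) or translation
(integer multiples) from two, reflection from three.  Replication
appends the images of the target atoms; an image within the merge
threshold of an existing atom is merged, the survivor taking the
*average* position.  The default threshold of 0.3 Å is small enough
never to fuse genuinely distinct atoms (shortest bonds ≈ 0.74 Å) and
large enough to absorb the drift of near-coincident images from slightly
unsymmetric starting structures.  Merge pairing is greedy
nearest-first with ties broken by lower atom id, and merging two
different elements raises a "symmetry clash" error instead of silently
averaging an O onto a Si.

Symmetrization reuses the same matching for order-2 operations
(inversion, reflection, C2): each atom pair (i, j) with op(pᵢ) ≈ pⱼ
moves to (pᵢ + op(pⱼ))/2 and (pⱼ + op(pᵢ))/2, which is exactly invariant
under the operation and idempotent.  Unmatched atoms are left untouched
and reported, never guessed.

Point-group detection centres on the mass-weighted centroid and tests
candidate operations against the atom set (element-matched, within a
0.1 Å default tolerance).  Candidate axes come from the inertia
eigenvectors, centre→atom vectors, same-element pair midpoints and
difference vectors, and cross products of centre→atom pairs (capped at
30 atoms to bound the quadratic candidate generation; the inertia and
pair candidates already cover larger systems).  Rotation orders 2–8 are
searched — enough for molecular point groups through D8h; the cap is a
parameter.  The Schoenflies symbol is assembled by the conventional
tree: linear systems → C∞v/D∞h; two or more axes of order ≥ 3 → cubic
and icosahedral families; otherwise the principal-axis tree (Dnh/Dnd/Dn,
Cnh/Cnv/S2n/Cn, then Cs/Ci/C1).  A single atom reports the full rotation
group "Kh".  Translations are building tools only and never enter
point-group detection.

## Scalar fields and surfaces

Grids store values as native R arrays (first lattice axis fastest) with
origin and three independent step vectors in angstrom; the Gaussian-cube
reader/writer converts bohr and the cube file's z-fastest ordering at
the boundary, writing enough digits ("%.10e") for 1e-10 round-trips.

Isosurfaces are extracted by **marching tetrahedra**: each voxel cell is
split into six tetrahedra sharing the main diagonal, a decomposition
chosen because it is consistent across neighbouring cells (shared faces
get the same diagonal), so the extracted surface is watertight with no
ambiguous configurations to disambiguate.  Surface vertices sit on
lattice edges at linearly interpolated crossings and are deduplicated by
edge key, which makes closed surfaces genuine 2-manifolds — the test
suite checks Euler characteristic V − E + F = 2 on a sphere, and that
every vertex of the |r| = 1 surface lies within one voxel diagonal of
the true sphere.  The cost relative to the classic 15-case cube table is
roughly twice as many triangles; for headless export that trade is
cheap.  Signed orbital display extracts the pair of surfaces at ±|v|.

Electrostatic potentials are bare point-charge Coulomb sums in atomic
units, evaluated in chunks of evaluation points (default 1000) so the
distance matrix never exceeds chunk × n_charges; the result is
independent of chunk size to ~1e-16 and the suite checks chunked output
against a brute-force double loop at 1e-10.  Surface coloring evaluates
the field at each mesh vertex — trilinear interpolation for grids
(clamped and flagged outside the box), the Coulomb sum for charges — and
the PLY exporter maps vertex scalars through a blue–white–red diverging
ramp with symmetric limits ±max|scalar|, so zero potential is always
white.

σ/π classification samples 500 point pairs (p, mirror of p) with a
fixed internal seed and compares interpolated amplitudes: antisymmetric
(π) when ≥ 95 % of samples above the noise floor (10⁻⁶·max|ψ|) flip
sign, symmetric (σ) when they keep it, mixed otherwise.  The 5 %
relative agreement tolerance absorbs interpolation error on realistic
lattices; the generator's lattices place z = 0 exactly on a lattice
mirror plane, making the parity of its analytic orbitals exact.

## The fixture generators

The generators define the conditions every test runs under; they are
first-class, tested code.

* Reference molecules are built at textbook geometries: benzene a
  regular hexagon with C–C 1.39 Å and C–H 1.09 Å; water O–H 0.9572 Å at
  104.52°; staggered ethane; a regular SiO₄ tetrahedron at Si–O 1.62 Å.
  Durene is *constructed*, not tabulated: four methyl fragments attached
  at ring positions 1, 2, 4, 5 through the fragment machinery, so the
  fixture exercises the code path it later tests.
* The charged platelet emulates a calcium-silicate-hydrate slab at the
  scale reported for large-system visualisation (9360 atoms): a 13-atom
  Ca₂Si₃O₈ motif replicated by translation operations into a thin
  12×12×5-cell slab.  Charges are element-based (Ca +1.5, Si +1.8,
  O −1.1, each ±0.2 uniform, seeded) and shifted to exactly zero net
  charge.  The coordinates are geometrically plausible, not a refined
  crystal structure — physical realism of the lattice is explicitly out
  of scope; what matters is the scale and the charge bookkeeping.
* Orbital sets are analytic atom-centred Gaussians (width 0.9 Å on ring
  carbons) combined with the six real ring-mode coefficient patterns:
  six pz combinations (π) and twelve s/in-plane-p combinations (σ),
  18 orbitals total, with plausible energies and occupations.  Single
  orbitals are normalized analytically, so the quadrature norm ≈ 1 check
  is a genuine test of lattice adequacy.
* The droplet packs n water molecules (minimum centre separation 2.5 Å)
  into a sphere with random orientations and a 1.85 D dipole along each
  molecular C2 axis — a static snapshot standing in for a dipolar-fluid
  Monte Carlo configuration; no simulation is performed.

What passing these tests shows — and does not.  The fixtures are exact,
noise-free geometries and smooth analytic fields.  Success demonstrates
the operators are correct (right transforms, right bookkeeping, right
conventions); it does not demonstrate robustness to experimental-quality
coordinates, near-degenerate symmetries at large tolerance, or cusped
all-electron densities, none of which the generators emulate.

## Problem sizes and determinism

The test suite and the acceptance script run the full 9360-atom pipeline
(64³ density lattice, ≈ 93 000 surface vertices, ESP at every vertex in
500-point chunks) in under a minute on one CPU; the remaining suites use
small molecules and 17³–33³ grids, chosen so the whole suite stays fast
enough to run on every change.  All randomness flows through explicit
seeds: fixture generators take a seed argument, the σ/π sampler uses a
fixed internal seed and restores the caller's RNG state, and the
acceptance script derives everything from its `--seed` flag.

## Known limitations

* Bond perception is purely geometric; no orders, no aromaticity, no
  periodic images.
* Point-group detection searches rotation orders ≤ 8 by default and
  reports a representative element list, not the full group multiplication
  table; icosahedral detection is classification-only.
* `detect_point_group` assumes an isolated molecule; translations are
  applied but never classified (no space groups).
* The `.mfx` dialect is versioned and documented here, but makes no
  claim of tag-level compatibility with any other XML chemistry format;
  unknown sections are preserved verbatim rather than interpreted.
* Geometry optimisation and any electronic-structure computation are
  delegated to external programs through compute plug-ins; the package
  only moves atoms and grids.
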