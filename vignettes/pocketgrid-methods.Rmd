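---
title: "Convex-hull and voxel-grid pocket detection: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Convex-hull and voxel-grid pocket detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketgrid)
```

## The model

A binding pocket is a concave patch of the protein surface. The observation
this package builds on is that concavity is visible in the convex hull of
the atom centers: over a cleft, hull triangles span the cavity mouth and
stand clear of the atoms beneath them, while over convex surface regions
every triangle hugs its own vertices. Each hull triangle therefore seeds one
candidate pocket:

* **Atoms.** An atom joins a facet's pocket when its center lies in the
  facet's *extreme box* — the axis-aligned box spanned by the per-axis
  minima/maxima of the three vertices — and its perpendicular distance to
  the facet plane is at most `atom_depth_cutoff`. With the outward normal
  `N = (x2 − x1) × (x3 − x1)`, that distance is non-negative for every atom
  (all atoms are inside the hull), so only the upper cutoff is active.
* **Empty voxels.** The structure's bounding box is partitioned into cubic
  voxels (`spacing`, default 1 Å, half-open intervals per axis; a voxel is
  occupied when it contains at least one atom *center* — no van der Waals
  radii enter the model). Each pocket atom contributes its nearest empty
  voxels from its 26-voxel shell, up to `k_max`, restricted to the facet
  box. These voxels are where ligand atoms could sit, and they carry the
  pocket's volume and cavity-surface measures. Voxels outside the hull are
  not explicitly removed: the per-atom neighbour rule already keeps the
  voxel set hugging the protein surface.

Candidates are then merged. Overlap between pockets is deliberately
asymmetric — `overlap(A, B) = |A ∩ B| / |A|` on atom sets — because a small
pocket wholly contained in a larger one should count as fully overlapping it
regardless of the size ratio. Two pockets are linked when either directed
overlap reaches `overlap_cutoff`; linked components are unioned. Because a
union can overlap a third pocket more than either part did, merging is
iterated to a fixed point. This makes the result idempotent and independent
of the order in which candidates are listed, which a single greedy pass
would not be.

## Pocket properties

The method needs a depth, a surface area and a volume per pocket but leaves
their exact definitions open; the package fixes them as follows and isolates
each behind one function so alternatives can be swapped:

* **depth** — the farthest any pocket point (atom center or empty-voxel
  center) sits below the pocket's contributing facet planes: the maximum
  over points of the minimum inward plane distance (Å).
* **surface** — `spacing²` times the number of voxel faces separating a
  pocket empty voxel from an occupied voxel: the cavity's atom-contact
  surface (Å²).
* **volume** — `spacing³` times the number of empty voxels (Å³).

## Biochemical typing and filters

Protein atoms are classified by exact (residue name, atom name) lookup in a
shipped TSV table covering the 20 standard residues: hydrogen-bond donors
(e.g. THR OG1, SER OG, TRP NE1), acceptors (GLN NE2, ASN ND2, ASP OD1,
GLU OE1), van der Waals carbons (ALA CB, LEU CD1/CD2/CG, …), ionic atoms
(LYS NZ, ARG NH1/NH2 positive; ASP OD2, GLU OE2 negative), sulfur (CYS SG,
MET SD) and aromatic ring carbons (PHE/TYR/TRP/HIS rings). Glycine
participates in nothing. Two conventions are worth noting: tyrosine appears
twice in the source table and the union of both rows is used (backbone O as
acceptor, backbone N and OH as donors, plus the ring); and the histidine
entries are encoded exactly as printed even where the printed atom names
(NE1, CD1) are not standard histidine nomenclature — the table is data, and
corrections are data edits, not code edits.

The **biochemical filter** keeps pockets offering at least `min_hba`
acceptor atoms, `min_hbd` donor atoms and `min_other` atoms of any remaining
class (defaults 1/1/1). The **physical filter** keeps pockets strictly
deeper than the ligand's length (largest inter-atomic distance) and with
more cavity surface than the ligand's area. The ligand's "area" is taken as
the convex-hull surface area of its atom centers, which is 0 for planar
ligands (fewer than four non-coplanar atoms); when a reference area is known
from elsewhere it can be supplied via `ligand_length`/`ligand_area` in
`pg_config()`, since no obvious geometric definition reproduces every
published ligand surface value.

Ligand atoms themselves are typed from connectivity (CONECT records): carbon
atoms on a cycle of carbons are ring members (bridge edges are removed from
the C–C bond graph first, so chain carbons between two rings are not
miscounted); oxygen bonded to N, P or Zn, or exclusively to carbon, is
unprotonated; calcium, or nitrogen bonded to exactly two carbons, is
protonated.

## Evaluation

Predictions on an unliganded structure are scored against the active sites
its liganded partner declares in SITE records (REMARK 800 supplies only the
site descriptions — SITE is the machine-readable record). For a pocket P and
site S, `cf = |residues(P) ∩ S| / |S|`, with residues matched on (residue
name, sequence number, chain, insertion code). Residue-to-ligand distances
are minima over atom pairs, computed in the deposited coordinate frames with
no superposition — the published worked pairs share a frame — and a warning
is raised when the two proteins' centroids disagree by more than 5 Å. A
benchmark over many pairs reports each protein's maximum cf and the fraction
with `max_cf ≥ 0.5`.

## Tunable parameters

| parameter           | default | units | role |
|---------------------|---------|-------|------|
| `spacing`           | 1.0     | Å     | voxel edge; the stated grid resolution |
| `overlap_cutoff`    | 0.8     | —     | pocket-merge linkage threshold |
| `atom_depth_cutoff` | 8.0     | Å     | facet-plane distance for pocket atoms |
| `k_max`             | 26      | —     | empty voxel neighbours kept per atom |
| `min_hba`/`min_hbd`/`min_other` | 1/1/1 | atoms | biochemical filter minima |
| `distance_cutoff`   | 3.5     | Å     | residue–ligand distance filter |
| `altloc`            | first   | —     | alternate-location policy |
| `dims_rounding`     | floor   | —     | grid dimensioning rule |

`spacing`, `overlap_cutoff` and `distance_cutoff` defaults are the method's
stated operating point. `atom_depth_cutoff` and the filter minima are free
parameters of the method (it states only their role, not values); 8 Å gives
pocket sizes of tens to a couple of hundred atoms on protein-scale inputs,
and the 1/1/1 minima are the weakest predicate that still demands donor,
acceptor and one hydrophobic/ionic/ring partner. Both are configuration, not
constants, and real-structure funnels are sensitive to them. Grid dimensions
use `floor(extent/spacing) + 1` voxels per axis so that an extent that is an
exact multiple of the spacing still receives its closing voxel;
`ceiling(extent/spacing)` is available as the alternative reading.

## Numerical choices

* Hull tolerance: `1e-9` of the bounding-box diagonal, used for visibility,
  degeneracy and containment tests. Points within tolerance of a facet plane
  are treated as on the hull surface, not beyond it.
* The hull is built by incremental insertion in input order with horizon
  re-triangulation; facets are always triangles and coplanar patches stay
  triangulated (a cube yields 12 facets), matching triangulating hull
  engines. Degenerate inputs (< 4 points, collinear, coplanar) raise a
  typed degeneracy error.
* Voxel membership uses half-open intervals; atoms exactly on the bounding
  box's maximal face belong to the last voxel.
* `empty_neighbors()` breaks distance ties lexicographically by voxel
  coordinate, so truncation at `k_max` is deterministic.
* Merged components are renumbered by their smallest constituent candidate
  id; reports format numbers with fixed precision — identical inputs give
  byte-identical reports.

## The synthetic generator

`make_planted_structure()` emulates the one geometric fact the method needs:
a concave cavity in an otherwise convex surface. It spreads `n_shell_atoms`
(default 400) quasi-uniformly (Fibonacci lattice plus seeded radial jitter
of ±0.15 Å) on a sphere of `shell_radius` 10 Å — about one pseudo-atom per
3 Å², protein-like surface density — and pulls atoms within `cavity_angle`
(45°) of the cavity axis inward by `cavity_depth · cos(π·θ/(2·θ_cap))`
(default depth 8 Å). Because a spherical cap of that width already bulges
`R(1 − cos 45°) ≈ 2.9 Å` above its rim plane, the *effective* concavity under
the mouth facets is about 5 Å. The axis defaults to `(1,1,1)/√3` so the
mouth triangles are oblique to the grid axes and their extreme boxes have
substance on every axis — an axis-aligned mouth would make the boxes
degenerate in one dimension. Atoms pulled in by at least `lining_fraction`
(0.7) of the full depth are the recorded ground truth, named from the
interaction-class table (donor, acceptor, vdW, ring, ionic, sulfur in
rotation) and declared as SITE `AC1`; the rest of the shell is glycine, so
only a pocket that actually reaches the cavity can pass the biochemical
filter. The toy ligand is a planar six-carbon ring with a hydroxyl-like
oxygen (length 4.14 Å, hull area 0), placed at the cavity mouth.

What the generator does *not* emulate: covalent geometry, residue
connectivity, side-chain rotamers, multiple chains, alternate locations in
context, or the irregular multi-lobed cavities of real proteins. Passing the
planted-recovery test therefore shows that the pipeline finds a clean
geometric cavity and recovers its declared lining exactly; it does not
certify recall on deposited structures, where the free parameters above and
the quality of SITE annotations dominate.

Test and acceptance runs use the generator at its default 400-atom size
(seconds per run) and smaller 150-atom variants for unit-level checks; the
planted-recovery study uses 20 seeded replicates.

## Known limitations

* Occupancy by atom center ignores van der Waals radii, so sub-voxel
  channels can appear between large atoms; this is inherent to the pure
  grid reading of the method.
* Pocket depth/surface/volume definitions are this package's own concrete
  choices for quantities the method names but does not define; absolute
  values are comparable within pocketgrid, not across programs.
* The ligand surface-area estimator (hull area of centers) is crude and
  degenerates to zero for planar ligands; supply a reference area when one
  exists.
* Cross-structure distances assume a shared coordinate frame; a
  superposition step is deliberately out of scope.
* The facet count of a triangulated hull is not unique when surface patches
  are exactly coplanar; engines may legitimately differ on such inputs.
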