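---
title: "Methods: the porous cranial implant pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the porous cranial implant pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cranioforge` implements the complete engineering workflow behind a
patient-specific porous PEEK cranial implant: imaging, mirror-reconstruction
design, porous scaffold generation, a linear static strength check, and
quantitative fitting assessment. This vignette is the package's own account
of the underlying models, the parameters that matter, and the numerical
decisions taken where the design space was genuinely open.

## The synthetic phantom and what it does (not) emulate

Every stage of the pipeline consumes data that, clinically, would come from
a patient: a CT volume, a skull surface, a fabricated implant, a laser
scan, an expert panel. The `synthetic_phantom` functions generate all of
these with controlled ground truth.

The skull stand-in is an **ellipsoid shell**: an outer ellipsoid (default
semi-axes 90 × 70 × 60 mm — lateral, antero-posterior, vertical) minus a
concentric inner ellipsoid offset by the wall thickness (default 6 mm,
within the adult calvarial range). This is a deliberate abstraction: the
pipeline's procedures depend only on *bilateral symmetry* and *shell
topology*, and the ellipsoid provides closed-form volumes
(4π/3 · (abc − a′b′c′)) that serve as exact oracles. The world frame puts
the midsagittal plane at x = 0 (left < 0), y antero-posterior, z vertical;
all lengths are mm.

What the phantom does **not** emulate: sutures, sinuses, variable wall
thickness, foramina, or any anatomical surface detail; nor does the CT
simulator model scanner physics (beam hardening, partial-volume blur,
metal artefacts) beyond additive Gaussian noise on a bone/air contrast
(defaults 1200 HU bone, −1000 HU air, σ = 30 HU). Passing tests on the
phantom therefore demonstrates the correctness of the *procedures* —
segmentation, symmetry analysis, CSG, elasticity, statistics — not their
robustness to anatomical complexity.

The defect is a spherical resection (default: radius 30 mm centred at
(−65, 15, 39) mm on the left parietal region; the defect geometry is a free
choice, and 30 mm produces an implant opening of clinically typical size).
The "manufactured" implant displaces surface vertices **outward** along a
smooth random field (Gaussian bumps, correlation length 15 mm) scaled so
the area-weighted *mean* displacement equals the requested amplitude; this
convention makes the mean-outward-deviation statistic recover the amplitude
directly, giving the fitting stage a known answer. The default amplitude,
0.33 mm, reproduces the scale of deposition-based printing errors. Scans
are area-uniform surface samples with isotropic Gaussian noise (default
σ = 0.05 mm) under an arbitrary rigid pose.

## Geometry backend: signed fields and marching tetrahedra

No mesh-boolean library is assumed: solids are represented implicitly as
signed distance fields (negative inside) sampled on regular grids, with
exact narrow-band distances (3 voxels) and sign from an exact ray-parity
test. CSG is then `min`/`max` algebra; surfaces are re-extracted by
**marching tetrahedra** on the Kuhn 6-tetrahedra cube split, with linear
interpolation along edges. Consequences worth knowing:

* Accuracy is set by the grid pitch; on smooth surfaces the isosurface
  error is second order in the pitch, so a 0.4–0.8 mm grid reproduces an
  ellipsoid-scale surface to a few micrometres.
* Triangles are oriented by the (exact) per-tetrahedron field gradient, and
  edge crossings that land on grid nodes are snapped and deduplicated, so
  outputs are watertight by construction.
* Grid origins are dithered by a fixed irrational sub-voxel offset;
  axis-aligned faces of analytically placed solids therefore never
  coincide with lattice planes, which would otherwise produce non-manifold
  pinch vertices.
* The "wrap" operation (closing gaps after merging mirrored halves) is a
  grayscale morphological closing (box structuring element, one voxel
  radius) applied to the field before meshing.
* `booleanSubtract()` accepts a *clearance* (cut tolerance, 0.05 mm in the
  reconstruction) that slightly enlarges the subtrahend — the standard
  remedy against paper-thin shells where the two operands share a surface,
  exactly the situation when subtracting a defective skull from its own
  reconstruction.

`reconstructSkull()` runs the whole split → mirror → merge + wrap →
subtract chain as field algebra on a single grid (the mirrored half is
obtained by trilinear resampling of the field through the reflection map),
which avoids materialising multi-million-triangle intermediate meshes. The
individual operations remain available and tested as mesh-to-mesh
functions.

## Midsagittal plane and alignment

The symmetry plane is initialised from the principal axis closest to the
lateral direction and refined by registering the surface to its own
reflection: at each iteration the reflected samples are matched to their
closest surface points and a **point-to-plane** linearised rigid update is
solved (6 × 6 normal equations); the plane is re-extracted from the
composed improper motion (eigenvector of eigenvalue −1). The worst 10% of
matches are trimmed each iteration so a unilateral defect cannot bias the
plane. Point-to-plane updates matter: point-to-point reflection ICP stalls
on smooth surfaces (tangential sliding) at convergence rates near 0.85 per
iteration, while the point-to-plane form converges in a handful of
iterations to numerical precision. `bestFitAlign()` (scan-to-reference
ICP) uses the same update for the same reason, after a coarse
centroid + principal-axes pre-alignment that tries the four proper sign
combinations and keeps the best.

## Implant design

* **Outer surface extraction** selects template faces within 0.8 mm of the
  skull surface with agreeing normals, closes pin-holes by face-neighbour
  voting, and keeps the *farthest substantial* connected patch from the
  skull centre (the outer table); bowtie boundary vertices are split so the
  swept side walls stay manifold.
* **Offset shell**: vertices sweep 4 mm inward along Laplacian-smoothed
  vertex normals (25 iterations; smoothing suppresses voxel-mesh normal
  jitter). Top/bottom/wall faces are tagged; a self-intersection
  diagnostic rejects sweeps whose inverted area exceeds 5% — isolated
  sliver flips at far-sub-voxel scale are tolerated because the
  parity-based field CSG downstream heals them.
* **Rim/core partition**: the rim is the set of points within the rim
  width (default 6 mm) of the side-wall surface, computed as complementary
  field cuts on one grid, so rim and core volumes sum to the shell volume
  by construction. Four screw holes (2 mm, through-cylinders along the
  local surface normal) are drilled near the boundary quadrants of the
  patch.
* **Diamond lattice**: the unit cell is the diamond crystal bond network —
  cylindrical struts along the four tetrahedral bond directions joining the
  two interpenetrating FCC sublattices — tiled over the core's bounding
  box as capsules, unioned and intersected with the core. The porosity
  solver bisects the strut radius until `(V1 − V2)/V1` is within 0.5
  percentage points of the target (V1 = core volume, V2 = scaffold volume,
  both measured on the same grid so discretisation bias cancels); the
  segment-distance field is computed once and reused across bisection
  steps. Strut fragments cut off at the core boundary are kept when they
  touch the solid rim (the printed part is one piece) and dropped when
  they float free.
* **Cell size** (default 2.5 mm) is the free parameter of the lattice: the
  target porosity fixes the strut radius, and the cell size then sets the
  pore diameter. At 70% porosity the 2.5 mm cell yields maximal inscribed
  pore spheres of about 1.35 mm — in the window reported to favour
  osseointegration. Pore diameters are measured by Nelder-Mead ascent of
  the clearance function (distance to the strut network minus the strut
  radius) from random interior void seeds, cross-checked in the tests
  against an exhaustive fine-grid distance transform.
* Porosity is reported for the core alone (the quantity the solver
  targets) *and* for the whole implant including the solid rim — the bulk
  envelope of a scaffolded region is ambiguous in general, so both numbers
  appear in the design manifest.

## Finite-element strength check

The assembly (skull = cortical bone, implant = PEEK, optional titanium
screws; isotropic linear elasticity, mm–N–MPa units) is meshed by
splitting every voxel whose centre lies inside a solid into the same six
Kuhn tetrahedra used by the isosurfacer. Meshing all regions on a common
grid makes interface nodes shared — the bonded-contact condition — without
any surface mesher. Two grid levels are used: the nominal pitch (default
1.5 mm) inside a box around the implant, twice that pitch elsewhere. Fine
nodes on the box boundary are tied to the average of their two coarse
master nodes (mid-edge and face-diagonal constraints); because every cube
face is split along the same low-to-high diagonal, these averages
reproduce the coarse element's linear field exactly, and a uniform-strain
patch test across the interface passes to machine precision (this is
asserted in the test suite). Boundary faces on the box planes are internal
interface, not free surface, and are excluded from load-patch candidates.

Boundary conditions follow the loading scenario of a resting head: all
degrees of freedom are clamped in a 5 mm basal slab, and a 50 N total load
is applied as consistent nodal forces from a uniform pressure over a
circular patch of the implant's upper outer surface grown face-by-face
until it covers 200 mm² (realised area within a few percent). A
"z-rollers" fixing mode (vertical supports plus a statically determinate
lateral restraint) exists for verification problems, where clamped
supports would pollute the uniform-stress solution.

The reduced stiffness system (hanging and fixed dofs eliminated through
the constraint expansion) is assembled in element chunks and solved by
supernodal sparse Cholesky factorisation. Per-element constant stress and
von Mises values are recovered, and a global equilibrium audit (reactions
at fixed dofs against the applied load) is reported with every solution;
it sits at the 1e-11 level on the full assembly. The solver refuses
free-floating components with an explicit message rather than returning a
meaningless least-squares answer.

Two modelling choices deserve emphasis. First, the implant enters the
model as the consolidated solid (rim + core envelope), not the
strut-resolved scaffold: a 1.5 mm voxel cannot represent ~0.7 mm struts,
and resolving them would require a pitch below half the strut diameter.
Solid-PEEK geometry overestimates the load-bearing section, so the
computed stresses are a lower bound for the lattice part; the safety
margin observed (peak implant von Mises around 1–2 MPa against a
99.9 MPa yield) is large enough that the qualitative conclusion — the
assembly carries the load — is insensitive to this simplification.
Second, the voxel mesh's staircase boundary is accepted: it perturbs local
surface stresses but conserves volume and stiffness to first order, and
the verification problems (patch test exact; cantilever within 15% of
Euler–Bernoulli at 1 mm elements, changing by under 10% on refinement)
bound the discretisation error.

## Fitting accuracy

Signed deviations are point-to-surface distances with an exact inside/
outside sign from ray parity. The headline statistic is the **mean outward
deviation**: the mean over strictly positive deviations only (points at or
inside the reference contribute nothing), with the outward fraction
reported alongside. Total fitting accuracy is decomposed as

* modeling component — designed reconstruction vs clean reference,
* manufacturing component — scanned (fabricated) surface vs design,

and the total is reported both as their sum (the decomposition convention)
and as the directly measured scanned-vs-clean deviation; the two differ in
general because outward-mean statistics do not add exactly. The ROI
variant restricts the statistic to a box (default: the defect bounding box
dilated by 5 mm). Gap analysis compares axis-aligned extents of the
implant's outer opening and the cavity opening, gap = cavity − implant per
axis.

The expert-panel assessment is a one-sided one-sample t-test of H0:
MAS ≤ 3 ("satisfactory") against Ha: MAS > 3, with the **per-expert mean**
across replicates as the observation unit (n = number of experts; a
per-rating variant is available). Zero-variance tables short-circuit to a
direct comparison with the null value, flagged as degenerate.

## Problem sizes and determinism

Default analysis sizes, chosen to keep a complete run in the ten-minute
range on one core: CT at 0.8 mm; reconstruction wrap at 0.8 mm (0.4 mm for
the high-fidelity check); shell CSG at 0.25–0.3 mm; lattice CSG at
0.15 mm; FEA at 1.5 mm fine pitch (about 120k elements on the phantom
assembly); 20k surface samples per deviation estimate; scans at
0.3–0.5 points/mm². Every stochastic operation takes an explicit seed and
restores the caller's RNG stream, so identical configurations reproduce
bit-identical outputs.

## Known limitations

* The phantom is not anatomical; results quantify procedure correctness,
  not clinical accuracy.
* Booleans are voxel-grid CSG: sharp edges are rounded at the voxel scale,
  and volume identities hold to the stated (1–2%) tolerances rather than
  exactly.
* The FE model is linear static with bonded interfaces: no contact,
  friction, plasticity, impact, or lattice-scale stress concentrations
  (the scaffold is not strut-resolved at the default pitch).
* Mean-outward-deviation decomposition is a convention; its two components
  only sum to the direct total when deviations do not change sign between
  stages.
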