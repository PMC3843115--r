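---
title: "Methods: voxel finite-element analysis of vertebral cement augmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel finite-element analysis of vertebral cement augmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

`spinefe` analyses the axial-compression mechanics of a three-vertebra
(T12--L1--L2) spine segment before and after vertebroplasty, the percutaneous
injection of PMMA cement into a vertebral body. The pipeline is
image-based: a 3-D greyscale volume and a tissue label map define the
geometry, bone elastic moduli are mapped element-by-element from greyscale,
and every labelled voxel becomes one trilinear hexahedral (hex8) finite
element on the regular grid. The segment is loaded under displacement
control between two rigid plates tied to cement end-housings, replicating a
materials-testing-machine protocol; the primary outputs are the segmental
stiffness $k$ (plate reaction force divided by applied axial displacement,
N/mm) and, for treatment comparisons, the per-element change in von Mises
stress at a common reaction force of 1000 N.

All quantities are in mm, N and MPa (1 MPa mm$^2$ = 1 N).

### Constitutive models

* **Bone** (trabecular and cortical shell): isotropic, $\nu = 0.3$, with an
  element-specific modulus $E = \max(a\,g + b, E_{\min})$ from the voxel
  greyscale $g$. QCT greyscale is assumed density-calibrated, so the default
  calibration is the identity ($a = 1$, $b = 0$) with floor
  $E_{\min} = 0.01$ MPa. A linear density--modulus law is the norm for
  QCT-based vertebral models; only the resulting modulus distribution
  moments are constrained by the reference data (mean 128.41 MPa, SD
  66.20 MPa), so slope and intercept remain configuration.
* **Nucleus pulposus**: isotropic; healthy $E = 1$ MPa, $\nu = 0.499$
  (nearly incompressible gel); degenerated $E = 4.9$ MPa, $\nu = 0.43$.
* **Annulus fibrosus**: orthotropic in cylindrical axes (1 = radial,
  2 = circumferential, 3 = axial), rotated per element about the disc axis.
  Healthy $E = (0.2, 35, 8)$ MPa with $\nu_{12} = 0.02$,
  $\nu_{13} = 0.065$, $\nu_{23} = 1.2$; degenerated
  $E = (0.53, 91.9, 21)$ MPa with $\nu = (0.022, 0.072, 1.32)$. The large
  $\nu_{23}$ is admissible for an orthotropic solid; positive definiteness
  of the 6x6 constitutive matrix is verified at construction. Shear moduli
  are not part of the reference property set but are required by any
  orthotropic formulation; the package defaults to Huber-type estimates
  $G_{ij} = \sqrt{E_i E_j}\,/\,\bigl(2(1 + \sqrt{\nu_{ij}\nu_{ji}})\bigr)$,
  which reduce to the isotropic relation when the axes degenerate. They are
  configurable through `material_orthotropic()`.
* **Cement** (augmented region): isotropic, $E = 2040$ MPa, $\nu = 0.3$;
  composite bone--cement behaviour is represented by scaling this modulus
  (fractions 1, 0.5, 0.25, 0.125), replacing -- not blending with -- the
  underlying bone modulus.
* **Housings**: isotropic, $E = 2450$ MPa, $\nu = 0.3$.

### Element formulation and solver

Elements are trilinear hex8 bricks with full 2x2x2 Gauss quadrature on
cubic voxels (default edge 1.4 mm, a convergence-tested element size for
this class of model). A uniform grid makes assembly exact and fast: all
isotropic elements sharing a Poisson ratio share one template element
matrix scaled by the element modulus; annulus elements get individually
rotated constitutive matrices, cached over the distinct cylindrical angles.
Element centroid stresses are the Gauss-point average of
$C\,B\,u_e$, which equals the centroid evaluation on a cube.

The bottom plate is fully fixed. The top plate is a rigid body whose
reference point (the mid-point of the plate, on the anterior--posterior
axis) carries the prescribed axial displacement; its lateral translations
and rotations are free by default, emulating load application through a
frictionless steel ball (`loading = "ball"`). A fully prescribed plate is
available as `loading = "locked"`. The constraint is eliminated exactly by
a sparse transformation $u = A z + b$, and the reduced symmetric
positive-definite system is solved by supernodal sparse Cholesky
factorization. The factor of the full segment runs to about a gigabyte, so
it is recomputed per solve rather than retained: chained solves
(calibration iterations, sweep cells) hold at most one factor at a time,
keeping long studies inside a few gigabytes. A diagonally preconditioned
conjugate-gradient path (relative tolerance $10^{-8}$) is provided for
memory-constrained problems. Equilibrium (top vs bottom reaction) is
reported with every solve; the direct path reaches machine precision.

Because the model is geometrically and materially linear, the experimental
"average load--displacement gradient" reduces exactly to
reaction/displacement from a single solve, and results at different loads
are exact linear rescalings -- which is what `scale_to_common_load()`
exploits for the 1000 N comparison convention.

## The synthetic phantom

No imaging data are distributed with this class of specimen study, so the
package generates its own: three stacked elliptic-cylinder vertebral bodies
separated by two disc slabs, potted in cement housings. Defaults (all
configurable in `phantom_spec()`):

| parameter | default | rationale |
|---|---|---|
| voxel size | 1.4 mm | matches the element-size convergence result |
| body semi-axes (lat x AP) | 16.8 x 11.2 mm | elderly female lower-thoracic/upper-lumbar body |
| body height | 23.8 mm | ditto |
| disc height | 8.4 mm | narrowed (degeneration-prone) disc space |
| cortical shell | 1 voxel | see below |
| nucleus radius fraction | 0.6 | nucleus occupies ~36% of disc cross-section |
| housing height | 5.6 mm | enough to spread the plate load |
| cement fill | 20% of body volume | clinical reference fill |

This yields 10,665 trabecular elements (the modulus-moment checks need at
least $10^4$) and about 22,000 elements / 76,000 dof in total, which one
CPU solves in roughly 15 s.

The trabecular greyscale is i.i.d. Gaussian clipped at zero. Clipping
inflates the mean and deflates the SD of the mapped modulus, so the parent
moments are pre-adjusted (`clipped_normal_params()`, closed-form truncated
normal moments inverted numerically) such that the *clipped* field
reproduces the reference mean and SD exactly in expectation. No spatial
correlation is imposed: the reference data constrain only the marginal
moments, and i.i.d. noise is the assumption-free default.

The cortical shell is one voxel thick with a constant greyscale of 2600.
This is a partial-volume homogenization: a ~0.35 mm compact-bone wall at
~10 GPa inside a 1.4 mm voxel column of otherwise trabecular bone gives an
area-weighted axial modulus of about
$0.25 \times 10000 + 0.75 \times 130 \approx 2600$ MPa, and the product of
shell width and modulus (the quantity that sets the shell's axial load
share) then matches the thin-wall original. Endplate slices (top and
bottom of each body) are cortical as well.

The cement region grows from the body centroid in deterministic order
(Euclidean distance, linear-index tie-break), producing the connected,
centrally seeded blob seen in post-treatment scans. No shape rule beyond
"central and connected" is claimed by the reference description, so the
distance ordering is the package's own deterministic choice -- it also makes
volume doubling/halving exact inverses of each other. Fill fractions are
measured against the whole vertebral body; because the cortical shell
cannot be augmented, the admissible maximum is the body's trabecular
fraction and requests beyond it fail with that maximum named.

**What the phantom does not emulate:** posterior elements and facet joints
(reported to matter little under pure axial compression, and meaningful
only with sliding contact, which is out of scope), anatomic asymmetry and
endplate curvature, CT physics (partial volume at tissue interfaces, beam
hardening, noise correlation), and wedge-fracture geometry. Tests passing
on the phantom therefore validate the *mechanics and the pipeline*, not
anatomical realism: conclusions that hinge on asymmetric load paths -- for
example how far stress redistribution propagates to the second adjacent
vertebra -- transfer only qualitatively, and in one documented respect (see
Limitations) not at all.

## Inverse disc calibration

Disc properties cannot be read from CT, so they are reverse-engineered: all
annulus moduli (Young's and shear) are scaled by a factor $f$ -- preserving
the anisotropy ratios -- and the nucleus modulus by a slaved factor, until
the simulated segmental stiffness matches a measured target (617 N/mm for
the reference specimen's pre-augmentation state). Poisson ratios are not
scaled: the reference healthy-to-degenerated transition changes them
non-proportionally (nucleus $\nu$ falls, annulus $\nu$'s rise slightly),
there is no defensible scaling rule, and scaling risks leaving the
admissible region.

A single stiffness measurement identifies a single parameter, so the
nucleus factor is coupled to the annulus factor rather than searched
independently. The coupling is a power law,
$f_{\mathrm{nuc}} = f^{\rho}$ with
$\rho = \log 4.9 / \log 2.625 \approx 1.647$, chosen so that it is exact at
both anchor points of the reference table: $f = 1$ reproduces the healthy
state (a fixed-point property a proportional coupling would violate), and
$f = 2.625$ -- the healthy-to-degenerated axial annulus ratio $21/8$ --
reproduces the degenerated nucleus value 4.9 exactly.

$k(f)$ is strictly increasing (verified numerically across the bracket), so
the root find is safe: the bracket $[1/16, 16]$ is walked geometrically to
enclose the target, then a secant step on $\log f$ with bisection safeguard
iterates until $|k - k^\ast|/k^\ast \le 10^{-3}$ (default; well inside the
sub-1% validation error the stiffness comparison aims for), with a cap of
60 stiffness evaluations. Targets outside the achievable range fail
immediately with the range reported. Each evaluation re-uses the assembled
non-disc stiffness blocks ($K = K_{\mathrm{other}} + f K_{\mathrm{ann}} +
f^{\rho} K_{\mathrm{nuc}}$), so a full calibration costs about seven
factorized solves and a single assembly.

On the default phantom the healthy-disc segment gives $k \approx 312$ N/mm
and the reference degenerated property set $\approx 703$ N/mm, so the
617 N/mm target is reached at $f \approx 1.9$ -- i.e. the calibrated state
is a stiffening of the healthy disc, consistent with the degeneration
narrative.

## Parametric treatment studies

Treatment operators are pure functions of (labels, greyscale, configuration):
materials are re-derived, never mutated, which makes every round trip
(double-then-halve cement, scale-then-unscale bone, switch disc state back)
bit-exact. The operators cover: activating augmentation per level (cement
regions of non-augmented levels revert to the underlying bone moduli);
scaling the augmented-region modulus; resizing the cement region by element
count along the same deterministic distance ordering; scaling all bone
moduli ("approximately halving and doubling" is implemented as exact x0.5
and x2 -- the hedge in the original description reflects greyscale
re-binning, while exact factors are cleaner and configurable); and
switching the disc state between the two reference property sets.

`run_sweep()` executes a grid of such configurations, records one stiffness
per cell, and -- for stress studies -- rescales each cell and its matched
untreated reference to the 1000 N convention before differencing von Mises
stresses element-by-element. Elements whose pre-treatment stress is below
$10^{-9}$ MPa have no defined relative change and are reported in an
explicit "undefined" bucket so that histogram mass (normalized by the total
element count of the vertebra) always sums to one. Bin edges default to
10-percentage-point bins over $[-100, 100]$ with open tails; the original
figures' binning is not recoverable, so the edges are configurable and the
defaults merely match their granularity. Failed cells are recorded and
skipped, never silently dropped.

## Numerical choices

* Threshold segmentation bins by half-open greyscale intervals; ties at a
  cut-point go to the higher bin. Each bin can be reduced to its largest
  6-connected component (flood fill) and regularized by morphological
  closing; erosion pads the array boundary with foreground so closing does
  not consume structures that touch the volume edge. When closings of two
  bins claim a voxel, the higher (denser) bin wins -- all deterministic.
* Level-set refinement of segment boundaries is omitted: on voxel phantoms,
  closing alone maintains geometric integrity, and the FE mesh is the voxel
  grid itself.
* The supernodal Cholesky is forced (`super = TRUE`); the heuristic
  default picks the simplicial path on these matrices and is several times
  slower. Singular systems (floating components) are diagnosed by a
  connected-component count of the element graph and reported as such.
* Degenerate inputs fail loudly and early: non-positive-definite material
  constants name the offending eigenvalue, impossible phantom geometries
  name the failing dimension, cement requests beyond the trabecular
  reservoir name the achievable maximum.
* Reported problem sizes: the test suite exercises the full default phantom
  (22k elements) in the acceptance checks and a reduced but fully
  structured segment (2.4k elements) elsewhere; both sizes are the
  package's choice of a fixture that keeps every code path -- cylindrical
  annulus, plate constraints, cement growth -- active.

## Limitations

* Linear elasticity only: no failure or strength prediction, no geometric
  nonlinearity, no time-dependent disc behaviour. The loading regime this
  mirrors stayed within the elastic range by design.
* Load control is represented only through the exact linear rescaling to a
  common reaction; a true force-driven solve with follower effects is out
  of scope.
* The idealized symmetric phantom damps long-range stress redistribution.
  After augmenting T12, the adjacent L1 shows the expected effect (most
  elements gain von Mises stress at 1000 N, with load funnelled toward the
  central column). In the *second* adjacent vertebra L2, however, the
  redistribution decays to the order of $10^{-3}$ percent through the
  intervening disc and the near-rigid bottom housing, and its direction is
  a diffuse slight increase rather than the majority decrease reported for
  real, asymmetric specimens whose cortices re-route load. The
  corresponding acceptance expectation is intentionally left failing
  rather than weakened: it marks a real boundary of the idealized
  geometry, not a solver defect.
* One stiffness target cannot identify annulus and nucleus factors
  separately; the power coupling is a declared modelling choice, and an
  independently measured nucleus state would replace it.
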