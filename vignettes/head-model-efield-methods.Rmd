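---
title: "Head models and induced-field computation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Head models and induced-field computation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tmsfield)
```

This vignette explains the models behind `tmsfield`, the assumptions they
rest on, the numerical choices that were genuinely open, and what the
package's synthetic validation does and does not establish about real
data. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The physical problem

A TMS pulse ramps the coil current at `dI/dt` of tens of amperes per
microsecond. In the quasi-static regime the induced electric field in
tissue is `E = -∂A/∂t - ∇φ`: a primary part set by the coil geometry alone
and a secondary part from charge accumulating at conductivity boundaries.
For small animals the secondary part is large: the head is small compared
to the coil, far from spherical, and the skull has large openings. The
package's job is to compute `E` on a cortical surface for arbitrary coil
placements over head models with exactly these features.

## Volume conductor model

Tissue is modelled as piecewise-homogeneous and isotropic: an outer body
surface (mean body tissue, default 0.33 S/m) and a skull compartment
(default 6.6 mS/m, a 1/50 ratio; both configurable). A rodent skull cannot
be described by nested closed inner/outer surfaces because of its
openings. Instead, the bone shell is bounded by **one closed 2-manifold**
— outer sheet, inner sheet, and smooth rim surfaces where the sheets
connect around each hole — floating inside the body surface. This
representation is exact provided the conductivity on both sides of the
openings (intracranial and body tissue) is equal, which the two-compartment
model assumes by construction. The trade-off: the intracranial space
cannot be given its own conductivity; the gain: any number of skull
openings with no special casing in the solver.

## Boundary element method

The surface potential `φ` satisfies the standard boundary integral
equation of piecewise-homogeneous conductors,

```
σ̄_k φ(x) = s(x) + (1/4π) Σ_l (σ_l⁻ − σ_l⁺) ∫_{S_l} φ(y) (y−x)·n̂(y)/|y−x|³ dS,
```

with `σ̄` the mean of the conductivities on either side of the surface
carrying the collocation point `x`, and `s(x) = p·(x−r_p)/(4π|x−r_p|³)`
for a current dipole `p` at `r_p`. Discretisation is **linear collocation**:
hat basis functions on surface vertices, equations enforced at vertices.
Three numerical choices matter:

* **Analytic element integrals.** The double-layer kernel integrals are
  solid angles; with a linear basis they reduce to the van
  Oosterom–Strackee solid angle plus analytic edge-log terms (the first
  moment of the solid-angle kernel over a planar triangle). Analytic
  integration keeps the near-singular interactions between the two skull
  sheets (0.7 mm apart, comparable to the edge length) accurate, where
  numerical quadrature degrades.
* **Closure-corrected diagonal.** At a mesh vertex the summed solid angle
  of the faceted surface differs from 2π by an O(h) rim term. The diagonal
  is set so each surface's own-row sum is exactly 2π, which makes a
  constant potential an exact discrete null vector — the same identity the
  continuous operator satisfies.
* **Deflation.** The insulated conductor determines `φ` only up to a
  constant. A rank-one update `A + c·11ᵀ/N` (with `c` the mean of `σ̄`)
  removes the null space; the LU factorisation is computed in place and
  cached. All quantities derived from `φ` are gauge invariant: the
  magnetic field integrals operate on per-surface de-meaned potentials,
  because a constant potential on a closed surface contributes exactly
  zero to the Geselowitz surface integral.

The magnetic field outside the conductor is
`B = B_∞ − (μ0/4π) Σ_l (σ_l⁻−σ_l⁺) ∮ φ n̂×(r−y)/|r−y|³ dS`, evaluated with
a one-point (centroid) linear-basis rule per triangle by default; a
three-point (edge midpoint) rule is available, but the sphere-oracle
comparisons in the test suite show the discretisation of `φ`, not the
surface quadrature, limits accuracy at the default resolutions.

## Reciprocity and the transfer solve

Rather than solving a TMS-specific problem per coil placement, the package
uses the reciprocity between TMS and the MEG forward problem: the
component of `E` at `r` along a unit dipole `ê` equals `-dI/dt` times the
flux of that dipole's magnetic field through the coil. The flux of the
secondary field is a linear functional `g` of the surface potentials, so
per placement one transposed solve `Aᵀt = g` converts every evaluation
point into three `O(N)` inner products. This is algebraically identical to
solving three dipole problems per point, and the package's per-point solver
(`solve_surface_potentials` + `geselowitz_bfield`) is tested against the
same oracles independently.

Sources and evaluation points must stay half a mean edge length away from
every surface — the discrete potentials cannot resolve nearer fields. This
mirrors the 1-mm clearance built into the evaluation surface for numerical
stability.

## Spherically symmetric model

The comparison baseline fits one global sphere to the hole-free crown of
the inner skull (algebraic least-squares fit refined by Gauss–Newton;
fitting region radius 8 mm by default). The field then follows from the
closed-form external magnetic field of a dipole in a spherically symmetric
conductor, again through reciprocity. Two properties are worth noting and
are asserted by tests: the result never depends on the radial conductivity
profile, and it is exactly tangential (zero radial component). The closed
form is valid only for evaluation points closer to the sphere origin than
any coil dipole; `run_comparison()` restricts the shared point set to the
worst-case validity radius over the grid when the sphere variant is
requested, and reports how many points were excluded.

## Coil model

A figure-of-eight coil is described by its winding envelope (24/47 mm
diameters, two wings of three layers of four turns, 9-mm stack, 2-mm
bottom insulation by default) and discretised as magnetic dipoles: each
turn is a planar circular loop at its layer height, with its enclosed area
split equally over azimuthal sample points; turn radii are spaced evenly
between the inner and outer winding radius, and the two wings carry
opposite signs. Defaults give 768 dipoles (2 wings x 3 layers x 4 turns x
32 samples); the single-layer simplification (`dipole_layers = 4.5`)
concentrates all three layers' weight at mid-height (256 dipoles). Winding
pitch is ignored (planar loops), and azimuthal convergence is established
by test: doubling the samples changes the sphere-model peak field by well
under 0.5 percent.

Orientation convention: the placement angle is the direction of the
primary E-field under the coil centre, measured in the scalp tangent plane
from the posterior–anterior reference (+x); `θ` and `θ+180°` give the same
placement up to field sign, so orientation grids span `[0°, 180°)` by
default (35 positions x 18 angles = 630 placements for the default
15 x 10 mm grid at 2.5-mm spacing — the spacing is chosen so that the
region tiles into exactly 7 x 5 positions).

## CT pipeline

Segmentation follows a deliberately simple recipe that high-contrast
micro-CT supports: the air/soft-tissue threshold is the midpoint of the
two dominant histogram modes; the soft/bone threshold is the first bin
after the soft-tissue mode falls below 1 percent of its height (the "end
of the soft-tissue peak", operationalised; the fraction is a parameter).
The body is the largest 26-connected component, smoothed by morphological
closure with a 2-mm spherical kernel; bone by a 1-mm kernel. Closures use
exact Euclidean distance transforms, so they are exactly idempotent and
reproducible across voxel sizes (kernel radius in voxels =
`round(radius/spacing)`).

Surfaces are extracted by marching tetrahedra at the 0.5 level of the
binary mask and remeshed isotropically (edge split / collapse with a
manifold link condition / valence-equalising flips / tangential
smoothing). Two findings from the phantom round-trip shaped the defaults:

* Mask pre-smoothing (a 3³ box filter) reduces staircase ripple on thick
  smooth structures but erodes features at the few-voxel scale — the
  0.7-mm bone sheets and rounded hole rims lose ~1.5 voxels. Raw
  extraction keeps every surface within one voxel of the generating
  geometry at 0.17-mm resolution, so no pre-smoothing is the default.
* Morphological closure adds fillets of up to about one voxel at the
  staircase terraces of near-flat surfaces. That is its purpose (it fills
  channels and smooths noise), but it means the closed-recipe surfaces
  agree with ground truth to ~2 voxels rather than 1; the no-closure
  recipe achieves the 1-voxel round-trip.

The brain mask is an input (the phantom supplies it; for real data the
command-line `segment` verb accepts a user-provided mask) — no automatic
brain segmentation is attempted. The evaluation surface is the boundary of
the brain mask minus the margin-dilated skull mask.

## The synthetic phantom

The phantom stands in for an undeposited micro-CT: an ellipsoidal body
(semi-axes 30 x 16 x 14 mm — the front half of the animal, head plus
anterior trunk), a thin cranial capsule (outer semi-axes
13.5 x 14.3 x 12 mm at x = +8 mm, 0.7-mm bone shell, 1.5-mm scalp
clearance at the crown, sub-mm lateral/ventral clearance), three skull
openings (a 20° posterior foramen and two 10° anterolateral orbital
openings, realised as spherical-cap cutouts with semicircular rim
profiles), a brainstem-like extension of the brain volume through the
posterior opening into the trunk, and a cortical evaluation surface
at least 1 mm below the inner skull sheet. CT synthesis voxelises the
surfaces (parity fill) at 0.17-mm default spacing with HU levels
-1000/+40/+1500 and seeded Gaussian noise, giving the three-mode histogram
the threshold recipe assumes.

Geometry rationale: the hole-funnelling physics — field concentration
where the brainstem leaves the skull — requires (i) a cranial cavity that
connects to the trunk essentially only through the foramen, with thin
current paths elsewhere, and (ii) evaluation points in and behind the
throat. A concentric full-body bone liner has neither and shows no
funnelling; the cranial-capsule phantom raises the near-rim field at the
same location by roughly 70 percent when the posterior hole is open,
comfortably demonstrating the effect's direction.

What the phantom does *not* emulate: real anatomical shape detail, tissue
inhomogeneity inside the body, CT artefacts other than Gaussian noise,
partial-volume intensities, and the eyes. Passing the phantom round-trip
therefore shows the pipeline machinery is faithful, not that segmentation
parameters are optimal for any particular scanner.

## Problem sizes used by tests and the acceptance script

Chosen as this package's validation conditions:

* Sphere oracles: 15-mm conductor, icosphere subdivision 4
  (2562 vertices); the silent-source check uses subdivision 5 because the
  cancellation it measures is an order of magnitude below the
  subdivision-4 discretisation error. Cortical points for the coil-model
  comparisons: icosphere at 13 mm radius (1-mm margin plus one mean edge
  length below the conductor).
* Mesh-halving comparison (`scripts/acceptance.R`): the default phantom
  (skull mean edge 0.67 mm, body 1.4 mm, about 12,000 unknowns) against
  itself remeshed to √2-longer edges; the in-suite variant runs the same
  comparison at skull edge 1.1 mm, where the correlation error is larger
  (coarser meshes), making the sub-1-percent assertion stricter.
* Segmentation round-trip: full 0.17-mm resolution (about 15 million
  voxels); the noise Dice check runs at 0.34 mm, where Dice is equivalent
  and eight times cheaper.

## Known limitations

* Linear collocation only; no Galerkin variant. Accuracy is anchored to
  analytic sphere oracles (relative error below 1 percent at subdivision
  4) rather than to a second solver.
* The remesher guards topology via the Euler characteristic, a manifold
  link condition and a symmetric surface-distance bound; it refuses
  targets coarser than the local feature size rather than attempting
  feature-aware simplification.
* Conductivities are isotropic and piecewise constant; no cerebrospinal
  fluid compartment, no eye compartment (the floating-skull construction
  would accept extra closed surfaces for either).
* The infinite-medium overestimation factor and the orientation-dependence
  summaries are geometry-dependent; on this phantom the peak-field
  overestimation factor is about 3, smaller than values reported for real
  rodent set-ups with deeper targets.
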