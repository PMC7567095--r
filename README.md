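# tmsfield

Estimating the electric field that transcranial magnetic stimulation (TMS)
induces in small-animal heads.

In rodent TMS the coil is large compared to the head, the head is far from
spherical, and the skull has large openings (the foramen magnum behind the
brainstem, the orbital openings behind the eyes). All three features bend
the induced current in ways that simple dosing models miss: the field
maximum is often posterior and medial to the coil centre, and for some coil
orientations the strongest stimulation appears in the brainstem rather than
under the coil. `tmsfield` implements an end-to-end pipeline for
quantifying these effects on individual head models:

* **Head-model construction from CT.** Threshold segmentation of a
  micro-CT volume into air, body and bone (thresholds found automatically
  from the intensity histogram), morphological closure with spherical
  kernels, marching-tetrahedra surface extraction with sub-voxel accuracy,
  and isotropic remeshing to a target edge length. The skull — holes and
  all — is represented as **one closed surface bounding the bone shell,
  floating inside the body surface**, which is valid whenever the
  intracranial and body conductivities are equal.
* **Coil models.** Figure-of-eight coils described by their winding
  geometry and discretised into magnetic-dipole quadratures (planar turns,
  several dipole layers across the wire stack), placed tangentially on the
  scalp at any position and orientation.
* **Field solvers.** The induced field `E(r)` is obtained by reciprocity
  with the magnetoencephalography (MEG) forward problem: the component of
  `E` along a unit current dipole at `r` equals `-dI/dt` times the flux of
  that dipole's magnetic field through the coil,

  `E_i(r) = -dI/dt * sum_k w_k n_k . B(e_i at r; r_k)`.

  `B` comes either from the closed-form spherically symmetric conductor
  solution (sphere model fitted to the inner skull) or from a
  **linear-collocation boundary element method** for piecewise-homogeneous
  conductors: analytically integrated solid-angle element kernels,
  closure-corrected diagonal, rank-one deflation of the potential gauge,
  and the Geselowitz magnetic-field formula with linear-basis surface
  quadrature. One transfer solve per coil placement makes whole-cortex
  evaluation cheap.
* **Comparison metrics.** Relative error `RE = ||E - E_ref|| / ||E_ref||`
  (components pooled into 3N-vectors), correlation error
  `CCE = 1 - cos(E~, E_ref~)` of the component-wise de-meaned fields,
  mean angular error, peak-location displacement, and hotspot restriction
  to points with `|E| > sqrt(0.5) * max|E|` — each per placement and
  summarised over placement grids (mean, sd, median, 2.3/16/84/97.7
  percentiles).
* **Synthetic phantom.** A rat-like two-compartment phantom (ellipsoidal
  body, thin cranial capsule with a foramen-magnum-like opening and two
  orbital openings, a brainstem extension through the foramen, and a
  cortical evaluation surface at least 1 mm below the skull) plus a CT
  synthesiser with the three-peak Hounsfield histogram the segmentation
  recipe assumes. All validation runs on this phantom and on analytic
  sphere oracles.

## Worked example

```r
library(tmsfield)

# synthetic rat-like head: body + floating skull-with-holes, cortex surface
ph  <- make_rat_phantom(phantom_spec(body_edge = 2, skull_edge = 1.1,
                                     eval_edge = 1.3))
sys <- build_deflated_system(assemble_double_layer(ph$model))

# default figure-of-eight coil, posterior-anterior, on the scalp above the
# cortex crown
cfg   <- run_config(phantom = ph$spec, region_extent = c(0.1, 0.1))
crown <- ph$evaluation$vertices[which.max(ph$evaluation$vertices[, 3]), ]
pl    <- placement_grid(ph$scalp, cfg, center = crown[1:2])[[1]]
coil  <- place_coil_tangential(build_figure8_quadrature(coil_spec()), pl)

E <- bem_efield(ph$model, sys, coil, dIdt = 50e6, ph$evaluation$vertices)
max(field_magnitude(E))
#> [1] 43.76055
```

At `dI/dt = 50 A/us` the peak cortical field on this phantom is ~44 V/m —
the order of magnitude expected for motor-threshold-level rodent TMS.
Comparing against the infinite homogeneous medium used by
line-navigation-style dosing:

```r
E_inf <- primary_efield(coil, 50e6, ph$evaluation$vertices)
relative_error(E_inf, E)                       # ~3.9: severe overestimate
max(field_magnitude(E_inf)) / max(field_magnitude(E))   # ~2.9x peak field
```

Full placement-grid comparisons across model variants (realistic 2C model,
body-only 1C, fitted sphere, infinite medium):

```r
cfg <- run_config(phantom = ph$spec)   # 15 x 10 mm grid, 10-degree step:
rep <- run_comparison(cfg)             # 630 placements
export_report(rep, "comparison-out")
```

A thin command-line front end with `phantom` / `segment` / `compare` verbs
is installed at `inst/cli/tmsfield.R`.

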