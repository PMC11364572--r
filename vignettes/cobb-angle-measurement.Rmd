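---
title: "Measuring coronal Cobb angles from labeled spine segmentations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring coronal Cobb angles from labeled spine segmentations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinecobb)
```

## The measurement problem

Degenerative (de novo) scoliosis is an adult spinal deformity, usually
lumbar, whose severity is graded by the coronal Cobb angle: the angle
between lines parallel to the superior endplate of the most tilted upper
vertebra and the inferior endplate of the most tilted lower vertebra of the
curve. It is conventionally measured on a standing AP radiograph. Patients
with low back pain, however, routinely receive lumbar MRI, and modern
segmentation models produce 3D labeled masks of every vertebra and
intervertebral disc (IVD) from those scans. `spinecobb` turns such label
volumes into Cobb angles.

The key idea is to measure discs rather than vertebral endplates. A disc is
geometrically simple — a slightly biconvex elliptical pad — and its upper
and lower surfaces abut the adjacent endplates: the upper surface of a disc
is, to good approximation, parallel to the inferior endplate of the
vertebra above it, and the lower surface to the superior endplate of the
vertebra below.

## The pipeline

For each disc mask the package:

1. **Extracts a surface mesh** at the 0.5 iso-level of the binary mask, in
   physical millimetres. The mesher is a tetrahedral decomposition of the
   voxel grid (a table-free marching-cubes variant): each sampling cell is
   split into six tetrahedra and each tetrahedron contributes one or two
   triangles with vertices at edge midpoints. The cube mirror parity
   alternates in a checkerboard so the shared tetrahedron diagonal has no
   preferred direction; a fixed diagonal measurably biases the vertex
   density and tilts downstream plane fits by a few tenths of a degree.
   The mask is padded with background, so meshes are always closed.
2. **Fits a mid-plane by PCA** over all mesh vertices: the centroid is the
   vertex mean, the normal the eigenvector of the vertex covariance with
   the smallest eigenvalue. Vertices are used unweighted.
3. **Splits the vertices** into an upper and lower half by the sign of the
   signed distance to the mid-plane (vertices exactly on the plane go to
   the lower half — a deterministic, measure-zero tie-break).
4. **Fits a plane per half**, again by PCA. These two half-planes estimate
   the two adjacent vertebral endplates.

All plane normals are sign-normalized to point cranially (non-negative
superior component; exact ties resolved toward the patient's right, then
anteriorly), so projected angles live in a single hemisphere.

### Projected angles and the candidate matrix

The **coronal angle** of a plane is the signed angle between the
superior–inferior axis and the projection of the plane normal onto the
coronal (left–right × superior–inferior) plane,
`atan2(n_R, n_S)` in degrees; positive values lean toward the patient's
right. The **sagittal angle** is the mirror image on the sagittal plane.
The two projections separate exactly: a purely sagittal tilt has coronal
angle zero. This is what makes the method robust for lordotic lumbar
levels, and it also yields the sagittal Cobb angle for free.

With per-disc upper/lower angles tabulated cranial to caudal, every
ordered disc pair (a cranial to b) produces a candidate measurement: top
vertebra = the vertebra below disc a (its superior endplate is the lower
half of a), bottom vertebra = the vertebra above disc b, and the candidate
angle is the absolute difference of the two signed projected angles.
Signed differences matter: opposite tilts add, as in the classic Cobb
construction. `n` discs give `n(n-1)/2` candidates, including
single-vertebra candidates from adjacent discs (a `min_span` option
excludes them if a minimum curve extent is wanted; the default keeps
them). The Cobb angle is the maximum candidate; ties break toward the
larger vertebral span, then the more cranial top level. With a single disc
in the field of view no candidate pair exists and the package reports the
angle table only — the endplates of the field-of-view-terminal vertebrae
are never extrapolated.

A reader-style measurement at chosen levels (`cobb_at_levels`) uses the
same table: the angle between the superior endplate of the requested top
vertebra and the inferior endplate of the requested bottom vertebra. It can
never exceed the maximal candidate, which is why an automatic maximum tends
to sit slightly above the average of readers who must first agree on
levels.

## Conventions and tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| iso-level | 0.5 | binary mask surface threshold |
| `min_half_vertices` | 30 | minimum mesh vertices per disc half for a stable PCA fit |
| `min_span` | 1 | smallest vertebral span of a candidate |
| QC `min_component_voxels` | 100 | fragment size that counts as a real disc piece |
| QC `min_coverage_fraction` | 0.6 | minimum disc footprint relative to the adjacent vertebral footprint |
| acceptance tolerance | 5° | clinically acceptable Cobb measurement error (strict `<`) |

The canonical frame is fixed: array axis 1 runs inferior→superior, axis 2
posterior→anterior, axis 3 left→right, in millimetres. Loading reorients
NIfTI and (axis-aligned) MetaImage volumes into this frame from their
header metadata; files without orientation metadata are refused rather
than guessed. Label semantics are externalized to a YAML scheme (a
SPIDER-style lumbar default ships with the package: vertebrae numbered
caudal→cranial from L5 = 1, discs offset by 200, the spinal canal label
ignored). Transitional anatomy such as an L6 is handled by supplying a
scheme with the extra level, not by code changes.

## Quality control

Segmentation failures that corrupt Cobb measurements are screened
automatically, mirroring what a human QC reviewer looks for: a missing
disc between two present vertebrae; a disc split into more than one
sizeable connected component (6-connectivity, components at or above
`min_component_voxels`); and a disc whose axial footprint covers less than
`min_coverage_fraction` of the mean adjacent vertebral footprint — the
signature of a one-sided collapsed disc segmented over only half the
endplate, which is precisely the failure mode that produces a wrong but
plausible-looking angle. QC is report-only; measurements are still
returned alongside the flags.

## The synthetic phantom

Real, expertly measured MRI cohorts cannot ship with a package, so
validation rests on a phantom generator with analytically known truth.
A phantom is a stack of alternating vertebral bodies and discs: elliptic
cylinders (defaults: vertebra 46 × 32 mm across, 28 mm tall; disc the same
footprint, 10 mm tall — average adult lumbar dimensions) cut by planar
interface surfaces whose coronal tilts are configured per endplate. The
true coronal angle of every endplate, hence every candidate and the true
maximal Cobb angle, follows directly from the configuration.

Three design points matter:

* **Rigid tilt, not shear.** Each structure's cylinder axis follows the
  local curve (the mean tilt of its bounding surfaces), so a tilted disc
  is a tilted disc, with its annulus wall perpendicular to its endplates —
  as in a real scoliotic spine. Extruding vertically instead (a sheared
  stack with tilted caps but vertical walls) makes the half-disc PCA fit
  attenuate a 10° tilt to about 6.6°, because the wall vertices drag the
  fitted plane: an unrealistic artifact of the wrong geometry.
* **Endplate doming.** Disc surfaces bulge 1.5 mm into the adjacent
  vertebrae (real discs are biconvex; endplate concavity of 1.5–2.5 mm is
  typical). The dome is symmetric about the disc axis, so it does not bias
  the fitted plane, but the curvature decorrelates the voxelization of the
  surface from the slice grid. Perfectly planar caps phase-lock with a
  3.29 mm slice grid and can swing a fitted endplate angle by several
  degrees depending on where the plane falls between slices — coherent
  staircase behaviour that irregular real anatomy does not exhibit.
* **Boundary jitter.** A smooth seeded random field (default amplitude
  0.3 mm, correlation length 6 mm) perturbs every interface, emulating
  the sub-voxel roughness of segmentation-model output.

A disc-collapse defect (coverage fraction with a one-sided shift)
reproduces the collapsed-disc QC failure mode. `random_study_config`
draws study-like cases: five vertebrae, a C-shaped curve with maximal
Cobb angle between roughly 6° and 38°, end-disc tilts at ± half the curve,
intermediate discs interpolating, per-disc wedging within ±2°, and a
supine sagittal tilt within ±12°. The two voxel spacings of interest are
0.90 × 0.47 × 0.47 mm (high-resolution 3D sequence) and
3.29 × 0.59 × 0.59 mm (standard sagittal T2).

The validation suite runs 20 such phantoms per resolution, a simulated
three-reader study on 30 phantoms, and 1000 random angle tables against a
brute-force enumeration — sizes chosen so the whole suite completes in a
few minutes on one CPU while keeping Monte-Carlo error well below the
asserted tolerances.

What passing phantom tests do **not** show: performance on real MRI. The
phantom has clean labels, elliptical cross-sections, planar-plus-dome
endplates and no pathology except the modeled defects; real discs have
herniations, Schmorl nodes, osteophytes and segmentation errors beyond
the modeled modes. The phantom validates the geometry and statistics of
the measurement chain, not the upstream segmentation model.

## Reader-agreement statistics

The reliability machinery mirrors a three-reader validation study:

* **MAE** — mean ± sample SD of absolute paired differences.
* **ICC** — two-way random-effects, absolute-agreement, single-measure
  ICC(2,1), computed from the two-way ANOVA mean squares with the F-based
  95% confidence interval, banded at the conventional 0.50 / 0.75 / 0.90
  cut-points. The guideline literature leaves the exact form open; ICC(2,1)
  is the strictest common choice for "different raters, absolute
  agreement", so numeric identity with other software should only be
  expected for the same form. Negative estimates are clipped to 0 and
  flagged.
* **Bland–Altman** — bias ± 1.96 SD limits of agreement (no small-sample
  t-correction), plotted against the ±5° clinical band.
* **Consensus level** — the median of an odd reader panel's levels under
  cranio-caudal ordering; for three mutually distinct levels, the middle
  one. With a 2–1 split the median is the majority level (L3, L3, L4 →
  L3). Even panels are refused rather than interpolated. (Worked examples
  in the clinical literature occasionally state the minority level in a
  2–1 split; this package follows the median definition.)
* **Acceptance simulation** — an automatic measurement at the reader's
  levels counts as accepted when it differs by strictly less than 5°,
  the clinically acceptable Cobb error; the acceptance fraction estimates
  how often a reviewing reader would keep the automatic value.
* **Level agreement** — per reader, the distribution of the summed
  absolute top + bottom level offsets against a reference, bucketed as
  exact / one level / two levels / more.

The reader simulator perturbs each endpoint of the true maximal pair to an
adjacent valid level with a configurable probability (respecting the
top-above-bottom constraint) and adds Gaussian noise to the angle read at
the chosen levels, floored at zero. Its closed-form consequences — the
half-normal MAE `σ√(2/π)`, the Gaussian acceptance fraction `2Φ(5/σ) − 1`,
and the slip-bucket distribution — are asserted against simulation in the
tests.

## Known limitations and numerical notes

* **Wedged discs.** The half-disc fit is attenuated toward the disc's mean
  orientation by roughly a quarter of the wedge angle per endplate,
  because the annulus wall follows the mean orientation. An 11° wedge
  therefore reads ~1.7° flat on each surface. This is a property of the
  disc-based method itself (wedge-shaped discs tilt the fitted plane
  toward the high side); the package deliberately adds no wedge-specific
  correction, which would trade robustness on pathological discs for
  accuracy on a rare geometry.
* **Coarse slices.** At 3.29 mm slice spacing a 10 mm disc spans three
  voxels; endplate angles of gently tilted discs (≲5°) can err by ±2–3°
  depending on grid phase even with doming. Cross-resolution agreement is
  therefore a population-level property (the phantom suite reports the
  cross-resolution ICC and the within-2° fraction), not a per-case
  guarantee at small curve magnitudes.
* **Sagittal tilt.** Separation of coronal from sagittal tilt is exact for
  pure tilts. Under a genuine 3D rotation by φ about the left–right axis a
  coronal tilt θ projects to `atan(tan θ / cos φ)`; for θ = 10°, φ = 20°
  that is a 0.58° inflation. Invariance is thus exact for flat endplates
  and first-order small for gentle curves, which is how the invariance
  suite probes it.
* **Degenerate inputs.** Empty or sub-2-voxel masks, collinear point
  clouds, halves below `min_half_vertices`, discs with interleaved SI
  extents, and requests for unavailable endplates all raise classed
  errors naming the structure, rather than returning numbers.
* The marching mesh on binary data places all vertices at edge midpoints;
  no sub-voxel intensity information exists in a label mask, so no
  interpolation refinement is possible or attempted.
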