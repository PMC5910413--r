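---
title: "Curvature-based phenotyping of metopic head shape: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curvature-based phenotyping of metopic head shape: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(craniocurv)
```

## The clinical problem

Closure of the metopic (midline forehead) suture spans a spectrum: from a
benign metopic ridge (BMR) — a palpable midline ridge with minimal
orbitofrontal deformity, a variant of normal — to true metopic
craniosynostosis (MCS) with trigonocephaly: a keel-shaped forehead and
retruded lateral orbital rims, usually treated with fronto-orbital
reconstruction.  There is no gold-standard severity threshold for surgery,
and practitioners disagree about the middle of the spectrum.  `craniocurv`
quantifies the two anatomical features that drive that decision — the
sharpness of the midline ridge and the retrusion of the supraorbital rims —
as signed mean curvatures on a 3D head surface, and clusters subjects into
mild/severe phenotypes without supervision.

The pipeline starts at a triangle mesh (STL from a CT bone reconstruction
or a stereophotogrammetric surface).  DICOM ingestion, bone thresholding
and surface reconstruction are upstream of this package.  CT (bone) and
stereophotogrammetry (skin) surfaces are analysed identically; no
cross-modality adjustment is applied, since curvature at the ~10 mm scale
of these regions is driven by the same underlying shape.

## Signed mean curvature

Mean curvature H is the average of the two principal curvatures.  We use
the convex-positive convention with respect to the outward surface normal:
a ridge reads H > 0, a scooped (retruded) area H < 0, so severity shows up
as a *large positive* mid-forehead curvature together with a *negative*
supraorbital curvature.  Meshes are in millimetres; H is reported in 1/m
(a factor of 1000).

The primary estimator (`meanCurvature()`) is the cotangent
Laplace–Beltrami operator with mixed-Voronoi vertex areas.  At vertex
$v_i$ with one-ring neighbours $v_j$:

$$\mathbf{K}_i \;=\; \frac{1}{2 A_i} \sum_{j}
  (\cot \alpha_{ij} + \cot \beta_{ij})\,(v_i - v_j),
\qquad
H_i \;=\; \tfrac{1}{2}\,\lVert \mathbf{K}_i \rVert\;
  \operatorname{sign}\!\left(\mathbf{K}_i \cdot \mathbf{n}_i\right),$$

where $\alpha_{ij}, \beta_{ij}$ are the angles opposite edge $(i,j)$,
$A_i$ is the mixed-Voronoi area of the one-ring (Voronoi pieces inside
non-obtuse triangles; area/2 at the obtuse corner and area/4 elsewhere in
obtuse ones, so the pieces exactly partition the surface), and
$\mathbf{n}_i$ is the outward vertex normal.  This is the standard discrete
mean-curvature operator; on a 100 mm icosphere at 2562 vertices it is
accurate to well under 1 %.

Numerical edge cases are handled explicitly:

* **Boundary vertices** (open stereophotogrammetry captures) have
  incomplete one-rings; they are flagged invalid and excluded from every
  region average rather than contributing edge artifacts.
* **Degenerate one-rings** whose mixed area collapses to zero are flagged
  invalid with a warning.
* **Orientation** is repaired at load time: windings are made consistent by
  breadth-first propagation across shared edges, then the whole surface is
  oriented outward by the sign of the enclosed volume (closed meshes) or by
  a majority vote of face normals against the centroid direction (open
  meshes, where signed volume is undefined).  The sign of H is meaningless
  without this step.

A second, independent estimator (`quadricCurvature()`) fits a least-squares
quadric $z = ax^2 + bxy + cy^2$ over the k-ring neighbourhood in the local
normal frame and reads off $H = a + c$ (heights measured along the inward
normal so the convention matches).  It exists to cross-check the cotangent
operator — the test suite requires the two fields to agree to within 5 % of
the field's interquartile range on a smooth head — and is *not* used for
the reported statistics.

`smoothField()` offers optional umbrella (area-weighted one-ring)
averaging for noisy scan data.  The default is 0 iterations: synthetic
fixtures need none, and smoothing trades noise for bias, so it is opt-in
per dataset.

## Regions of interest

Three regions are segmented from four landmarks (glabella, anterior
fontanelle, left/right superior orbital rim polylines).  Landmarks are
snapped to the exact nearest surface point on load; a snap distance above
10 mm aborts with the landmark's name, since that almost always means a
coordinate-frame mismatch rather than annotation error.

* **Mid-forehead strip** — the published definition is a rectangular
  region of 10 mm width from glabella to anterior fontanelle.  On a curved
  surface we realise it as a slab: vertices within ±5 mm of the midline
  plane (through glabella, fontanelle and the mesh centroid), restricted
  to the axial extent of the glabella→fontanelle segment, and to the
  landmark side of the head (without that last half-space the same slab
  also cuts the occiput).  When the two landmarks are antipodal about the
  centroid — possible on synthetic fixtures — the plane is completed with
  an arbitrary vector containing the axis and the half-space filter is
  dropped, since there is no "back wall" to exclude.
* **Supraorbital bands** — vertices within 10 mm of the rim polyline,
  *above* it (positive displacement component along an `upHint`
  direction), and projecting inside the polyline's arc-length span.  The
  10 mm figure is interpreted as band depth above the rim; the published
  description gives "10 mm width" for both regions without defining the
  measurement axis, so both widths are configurable.
* The medial/lateral extent of each band is taken from the supplied rim
  polyline; we do not infer the "mid superior orbital rim" point.

Whether the original regions followed the surface geodesically or were
projected rectangles is not recoverable from their description; the
slab/band construction is reproducible from point landmarks alone and
needs no geodesic machinery, which is why we chose it.

Region means are **area-weighted**: $\bar H = \sum w_i H_i / \sum w_i$
with mixed-Voronoi areas as weights, which makes the statistic invariant
to tessellation density (an unweighted vertex mean would drift with
remeshing).  The original work segmented interactively; replacing a manual
outline with landmark-driven geometry makes the regions deterministic and
re-checkable, at the cost of requiring landmarks.

## Subject features and group statistics

Each subject contributes `h_mid` (mid-forehead strip mean), `h_orb_left`,
`h_orb_right`, and their average `h_orb` — the published summaries report
one pooled "right/left lateral orbital areas" value, and per-subject
averaging (rather than pooling vertices) keeps the two sides equally
weighted regardless of band vertex counts.  Per-side values are retained.

Group comparisons use Welch's unequal-variance t-test (two-sided):
the groups being compared have unequal sizes (16 vs 27) and unequal
spreads, so the pooled-variance assumption is not defensible; Student's
test is available via `varEqual = TRUE`.  SDs use the sample (n − 1)
denominator.  Two groups that are constant and equal yield p = 1 with a
warning instead of an error, keeping batch reports total.

## Severity clustering

`kmeans2()` is Lloyd's algorithm with k-means++ initialisation, a fixed
seed, 50 restarts by default (best within-cluster sum of squares kept),
convergence on stable assignments or 300 iterations, and an emptied
cluster re-seeded at the point farthest from its centroid.  k is fixed at
2 — the mild/severe dichotomy is the clinical question; no model
selection is performed.  Results are deterministic given (features, seed,
restarts) and invariant to subject order (rows are canonicalised by
subject id before clustering).

The default feature space is 2-D `(h_mid, h_orb)`, matching the published
two-column summaries and severity scatter; a 3-D option
`(h_mid, h_orb_left, h_orb_right)` is exposed because the narrative
mentions "the three segmented regions" — which of the two the original
analysis used is not decidable from its description.  Features are
clustered raw: both axes are curvatures on comparable scales (group SDs
5–7 1/m), so standardisation is unnecessary (and available via
`standardize = TRUE`).  The *severe* cluster is defined as the one with
the larger `h_mid` centroid, ties broken towards the smaller `h_orb`;
agreement with clinicians maps severe↔operative, mild↔conservative.

## What the synthetic generators emulate

Three generators make the pipeline testable without patient data:

* `makeFixture()` builds surfaces of known analytic curvature — icosphere
  (H = 1/r), open cylinder (H = 1/(2r)), plane (H = 0), dented sphere
  (sign test) — which certify the estimators against closed forms.
* `makeHead()` builds an ellipsoid head (default semi-axes 65 × 80 × 75 mm,
  infant-head scale) deformed along the surface normal by a midline
  frontal Gaussian ridge (amplitude 1→4 mm and lateral width 14→6 mm as
  `ridgeSharpness` goes 0→1) and bilateral supraorbital Gaussian scoops
  (depth 0→7 mm with `orbRetrusion`, ~12 mm radius, centred just above
  the emitted rim polylines).  The amplitudes were chosen once so the
  dials sweep the strip means through a clinically plausible range with
  the scoop driving `h_orb` negative at high retrusion.  Deformations and
  the icosphere vertex set are exactly symmetric under x → −x, which is
  what lets the tests assert left/right feature equality.  The generator
  emits ground-truth landmarks and region membership, so it certifies
  *segmentation geometry* and *monotonicity* (sharper dial ⇒ larger
  `h_mid`; deeper dial ⇒ smaller `h_orb`).  It does **not** emulate
  anatomy (no temporal fossae, no orbit openings, no scanner noise
  spectrum or holes), so passing tests certify the algorithms, not
  absolute clinical curvature values.
* `simulateCohort()` draws feature-level cohorts from bivariate normals
  parameterised by the published group summaries (severe cluster: 16
  subjects, `h_mid` 38.6 ± 7.1, `h_orb` −6.7 ± 4.7 1/m; mild: 27
  subjects, 28.0 ± 4.9, 10.6 ± 5.5 1/m).  The between-feature correlation
  is not recoverable from those summaries, so ρ defaults to 0 and is
  exposed; left/right orbital values are split as `h_orb` ± a small
  N(0, 0.5) perturbation so their average is exactly `h_orb`.  Cohort
  sizes default to the published 16/27 split.  What the feature-level
  simulation cannot test is everything upstream of the features — that is
  the head generator's job.

All generators are bit-reproducible from their seed and restore the
global RNG state.

## Problem sizes and numerical defaults

The simulation studies in the test suite use 200 cohorts of 16 + 27
subjects for clustering recovery (mean agreement and centroid recovery)
and 500 replicates for test power — sizes at which the Monte Carlo error
of the reported means is well below the margins being asserted.  Mesh
tests run on icospheres at subdivision levels 3–5 (642–10242 vertices)
and heads at level 4 (2562 vertices), where the cotangent operator's
sphere error is ≲ 0.5 %.  Fixed numerical choices: vertex-merge tolerance
1e-6 mm (below any scanner's precision — it collapses STL triangle-soup
duplicates only); landmark snap limit 10 mm; region widths 10 mm
(configurable); k-means seed 0 and 50 restarts.

A note on power: at the published *surgical/non-surgical* group
parameters (39.0 ± 6.9 vs 27.7 ± 4.6, n = 16/27), the Welch test on the
mid-forehead feature has analytic power ≈ 0.84 at the p < 10⁻⁴ threshold;
the supraorbital contrast (−5.9 ± 5.7 vs 10.2 ± 6.3) has power ≈ 0.9999.
A single observed cohort clearing p < 10⁻⁴ on both features is entirely
consistent with this; simulation replicates will clear it on the
supraorbital feature essentially always and on the mid-forehead feature
roughly five times in six.

## Limitations

* Landmarks are required inputs; there is no automatic landmarking.
* The slab/band regions approximate geodesic strips; on very curved
  surfaces a Euclidean band is slightly narrower at high-curvature spots
  than its geodesic counterpart.
* Curvature at boundaries is undefined by construction; subjects whose
  regions of interest touch a capture boundary lose those vertices.
* The severity clustering is descriptive, not a treatment rule: it
  reproduces a consensus boundary in feature space, and discordant
  subjects are exactly the cases worth a second clinical look.
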