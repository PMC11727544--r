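---
title: "Comparing ROI-based and streamline-based bundle segmentation on synthetic tractograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing ROI-based and streamline-based bundle segmentation on synthetic tractograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the package answers

Virtual dissection extracts a named white-matter bundle — here the arcuate
fasciculus (AF), its indirect anterior (fronto-parietal) and posterior
(temporo-parietal) segments, and the inferior fronto-occipital fasciculus
(IFOF) — from a whole-brain tractogram. Two families of methods dominate
clinical practice:

* **ROI-based filtering**: the operator draws inclusion ("Any Part") and
  exclusion ("No Part") regions on anatomical images; streamlines are kept
  when they satisfy the conjunction of all filters, with a midline slice
  filter discarding commissural crossers. Selection is *indirect*: a voxel
  admits every streamline that happens to pass through it.
* **Streamline clustering**: streamlines are grouped by shape under the
  minimum-average-direct-flip (MDF) metric, each cluster summarized by a
  medoid prototype, and the operator iteratively keeps, discards, and
  re-clusters prototypes. Selection acts *directly* on the fiber
  reconstructions.

The package implements both engines and the downstream comparison: a
voxel-based shape analysis whose headline statistic is the **irregularity
index** (a compactness score; an ideal cylinder is the optimum, and
streamlines deviating from the bundle's main course raise it), followed by
a per-bundle two-sided paired *t*-test and Cohen's *d* on paired
differences across a cohort. The scientific expectation is that ROI-based
segmentations carry recurrent artefactual streamline populations and so
score systematically *higher* irregularity than streamline-based
segmentations of the same bundle in the same subject.

Because clinical tractograms of this kind are not publicly deposited, the
cohort is synthetic: a phantom generator produces labeled tractograms whose
bundle and artefact populations make every stage of the pipeline testable
against ground truth.

## The phantom

The phantom lives on a 180 x 216 x 180 voxel grid at 1 mm isotropic
resolution with an identity affine (world mm = voxel index), an MNI-like
extent that keeps recipe coordinates anatomically readable. The sagittal
midline sits at x = 90 mm; all bundles occupy the left half, standing in
for the healthy hemisphere. Axes follow RAS: y runs posterior to anterior,
z inferior to superior.

Each bundle is a tube around a fixed centerline (an arc for the AF, a
fronto-parietal arch for the anterior segment, a near-vertical
temporo-parietal course for the posterior segment, and a long
antero-posterior course funneled through a stem for the IFOF). A generated
streamline is the centerline plus:

* a constant transverse offset whose magnitude is Rayleigh-distributed at
  scale `radius` (default 2.5 mm for bundles, 2 mm for artefacts) and whose
  direction is uniform in the plane normal to the local tangent;
* two low-frequency sinusoidal jitter waves (amplitude bound `jitter_amp`,
  default 1 mm) giving the tube a realistic fray;
* random arc-length trimming of up to `end_trim` (default 3 mm) at each
  endpoint.

Default population sizes are 500 streamlines per bundle, 100 per artefact
pattern, and 1000 background streamlines, i.e. 3500 per subject — large
enough that the ROI-vs-clustering contrast is visible, small enough for a
desk-scale cohort. Inter-subject variability is a rigid rotation (up to
4 degrees about a random axis) plus anisotropic scaling (within 4%) of all
control points about the grid center; both limits are configurable but
capped (10 degrees, 10%) so that the axis-aligned recipe boxes remain
meaningful.

Six artefact populations reproduce the recurrent contamination patterns of
ROI-based dissection, each *designed to survive the inclusion filters of
its target recipe*:

* `parietal_ending` — follows the AF's longitudinal course, dips through
  the axial temporal waypoint, then bends back up to terminate dorsally in
  the parietal region: it crosses **both** AF waypoint ROIs yet is not an
  AF streamline.
* `u_fiber` — short (< 40 mm) arcs connecting adjacent gyri next to an
  inclusion ROI; one variant pierces the coronal waypoint (leaking into the
  anterior segment), the other the axial temporal waypoint (leaking into
  the posterior segment).
* `dorsal_loop` — passes the IFOF stem and loops back dorsally toward the
  frontal cortex. One sub-population returns through the territory of the
  extended dorsal exclusion and is caught by it; the other arcs higher
  still and leaks even past the extended exclusions — the residual
  contamination that motivates cleaning by direct streamline selection.
* `projection_vertical` — mimics the AF course, then drops with a vertical
  trajectory through the insular/projection territory; the AF recipe's
  insula exclusion block removes these.
* `commissural` — crosses the midline plane; removed by the slice filter
  present in every recipe.
* `background` — smooth random clutter polylines in the hemisphere.

What the phantom does **not** emulate: curving fanning terminations into
cortex, crossing-fiber-induced local direction noise, lesion-induced
displacement, and scanner/tracking biases. Passing tests therefore
demonstrate that the *engines and statistics* behave as specified under
known geometry, not that either segmentation approach is clinically
superior on real data.

## ROI recipes

Recipes are conjunctions of axis-aligned boxes (the reproducible analog of
hand-drawn ROIs; NIfTI mask ROIs are equally supported) with per-term
`any_part` / `no_part` logic plus the midline slice filter:

* **AF**: coronal waypoint box in the deep white matter of the arc's
  longitudinal portion + axial waypoint box under the temporal descent
  (both `any_part`) + insula exclusion block + midline filter.
* **AF anterior segment**: the same coronal waypoint; the axial ROI
  enlarged to a full plane segregating temporal terminations, as
  `no_part`.
* **AF posterior segment**: the same axial waypoint; the coronal ROI
  enlarged to a full plane segregating frontal terminations, as `no_part`.
* **IFOF**: a stem waypoint box at the external/extreme-capsule analog,
  dorsal and ventral exclusions above and below the stem and — by default
  (`ifof_extended = TRUE`) — their extensions to the axial plane, which
  catch dorsally looping and ILF-like returning streamlines.

Two conventions matter numerically. Streamlines are supersampled at
<= 0.5 mm (half a voxel) before point-in-region tests, because vertex-only
testing misses thin ROIs pierced between vertices. Slice crossing uses
strict sides: a streamline touching the plane without points on both sides
is not a crosser — a deterministic tie-break.

ROI coordinates are stated for the undeformed phantom anatomy; when a
subject deformation is supplied, box *centers* follow it while extents stay
fixed. This mirrors the clinical workflow, where ROIs are drawn on each
patient's own anatomy, and it is why small rotations are compatible with
axis-aligned boxes.

## Clustering engine and template policy

The MDF between two streamlines resampled to `n_points` (default 20)
equidistant points is the smaller of the mean pointwise distance in direct
and in reversed order — invariant to tracking direction. Clustering works
in a dissimilarity embedding: each streamline is represented by its MDF
distances to `min(40, n)` reference streamlines chosen by farthest-first
traversal, k-means partitions the embedding, and each cluster is summarized
by its medoid (the member minimizing summed MDF to co-members). All
stochastic steps take explicit seeds.

The interactive workflow (pick / invert / remove-unselected / select-all /
expand) is exposed as `apply_selection_op()`. Its scripted surrogate,
`auto_segment_by_template()`, replaces the operator's eye with a template:
cluster the active set with an increasing cluster-count schedule (default
50, 100, 200, 400), keep clusters whose prototype lies within `tau_select`
(default 15 mm) of the nearest template streamline, remove the rest,
re-cluster; finally keep individual streamlines within `tau_final` (default
8 mm) of the template. On phantoms the template is the subject's deformed
generator centerline — deliberately *not* the ground-truth member
streamlines, so the surrogate cannot trivially copy labels. The thresholds
are free parameters of the surrogate, not claims about operator behavior;
with the default dispersion (2.5 mm Rayleigh scale) the 8 mm final gate
keeps ~98% of bundle members while the designed artefacts sit well beyond
it.

## Shape measures

A segmentation is voxelized (every voxel hit by a <= 0.5 mm supersampled
point, half-open voxel-center convention), then:

* `mean_length` — mean streamline arc length;
* `span` — mean endpoint-to-endpoint distance;
* `volume` — flagged voxels x voxel volume;
* `surface_area` — exposed voxel faces (6-connectivity) x face area;
* `diameter` — of the equivalent cylinder, `2 * sqrt(volume / (pi * mean_length))`;
* `irregularity` — `surface_area / (pi * diameter * mean_length)`;
* `curl` and `elongation` as derived conveniences.

Exposed-face counting was chosen over a mesh estimator because it is
deterministic and exactly testable (a single-voxel column of length 100 mm
has exactly 101 voxels and 406 faces, giving irregularity 1.1396 by
arithmetic). The cost is a known discretization bias: the staircase surface
of a digitized cylinder exceeds the true lateral area by a factor of about
4/pi (about 1.27), so even an ideal axis-aligned cylinder scores about 1.3
rather than the analytic 1. Because both segmentation methods share the
estimator, the *comparison* — the package's actual statistic — is
unaffected; absolute irregularity values should be read relative to the
estimator's own cylinder score, and sub-voxel translation robustness (~5%
for realistically dense bundles) degrades for very thin or sparse line
sets.

## Statistics

Per bundle and method, descriptive statistics use the sample standard
deviation (n − 1) and linear-interpolation percentiles. The comparison is a
two-sided paired *t*-test on per-subject irregularity pairs with
`cohen_d = mean(d) / sd(d)` on the paired differences (so `t = d * sqrt(n)`
exactly); a Shapiro–Wilk p-value of the differences is recorded per bundle,
and the pipeline warns rather than aborts when it falls at or below 0.05.
Significance is assessed at alpha = 0.05 with no multiple-testing
correction across the four bundles (a deliberate mirroring of common
practice in this setting, noted rather than endorsed). Two degenerate cases
are handled explicitly: identical paired vectors return the exact null
(t = 0, p = 1, d = 0), while zero-variance differences with nonzero mean
are refused as a degenerate sample.

## Reproducibility and problem sizes

A master seed fans out deterministically: subject i uses
`master_seed + i`; within a subject, bundle generation uses
`seed + 1000 * j`, artefacts `seed + 777`, and the clustering of bundle j
`seed + 31 * j`. Configs are YAML over a versioned schema; unknown keys are
rejected so silent drift cannot occur. The default experiment (25 subjects,
3500 streamlines each, both engines, four bundles) runs in a few minutes on
one CPU; unit tests exercise the same machinery on reduced cohorts (2–3
subjects, 60-streamline bundles), sizes chosen so the full suite stays
fast while the headline claim is still verified at the full 25-subject
scale in the acceptance checks.

## Known limitations

* Absolute irregularity values carry the face-count staircase factor
  (~4/pi) relative to mesh-based estimators; comparisons are unaffected.
* The template-guided policy is a scripted surrogate for human selection;
  its thresholds are documented free parameters.
* Artefact prevalences are free parameters of the phantom (no quantitative
  prevalences exist to calibrate against); defaults were fixed once at
  values that make each designed confound clearly expressed.
* Only downsampling is performed by default when resampling tractograms to
  a target count; duplication-based upsampling must be requested explicitly
  because it biases density-based measures.
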