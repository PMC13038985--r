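---
title: "Measuring cortical-bone gradients: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cortical-bone gradients: models, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`bonegrad` quantifies how cortical bone's void microstructure — porosity and
vascular-canal diameter — varies along a long bone and through the cortical
wall, and how those gradients relate to apparent compressive stiffness. This
vignette is the package's account of the measurement model: what each stage
computes, the conventions it commits to where the underlying field practice
is ambiguous, and what the synthetic-phantom validation does and does not
demonstrate.

## The measurement model

### Segmentation

Input volumes are 8-bit grayscale stacks `[y, x, z]` with isotropic voxel
size (5.8 µm by default, a typical ex-vivo micro-CT resolution at which
vascular canals of roughly 40–200 µm are resolved while the
lacuno-canalicular network is not). A voxel is bone iff its intensity lies in
the inclusive window `[lower, upper]` (default 80–255). No smoothing or
beam-hardening correction is applied — segmentation is a pure intensity rule,
so a noise-free rendering thresholds back to its generating labels exactly.

Despeckling then removes, independently on every transverse slice, each
foreground component with *strictly fewer* than 25 pixels. Two conventions
are ours to declare, since standard desktop tools do not document them
precisely: components are 8-connected (the conventional choice for
foreground; a `connectivity = 4` switch exists), and "smaller than 25" is the
strict inequality (a 24-pixel blob is removed, a 25-pixel blob survives).
Only white (foreground) speckles are touched; removing black speckles (small
pores) would bias porosity and is deliberately not part of the default path.

### The bone envelope

Porosity is void volume over *bone area*, so the bone area — the region
inside the periosteal boundary, including intracortical pores, excluding the
exterior and the medullary cavity — must be constructed from the mask. Per
slice, the bone mask is morphologically closed with a Euclidean disk
(default radius 300 µm), implemented exactly as two distance-transform
thresholds rather than a rasterized brush so that circular boundaries survive
voxel-exactly; interior holes are then filled. Of the interior background
components of the closed mask, the largest (above a 10,000 µm² floor) is
identified as the medullary cavity and kept as a separate mask; all smaller
interior components are intracortical pores and are filled into the
envelope. The closing radius must be smaller than the cavity radius — a disk
that does not fit inside the cavity would close it over; with the default
300 µm the package supports cavities down to ~350 µm radius.

### Porosity

`roi_porosity()` is exact integer voxel counting: non-bone voxels inside the
reference region divided by region voxels. The reference region is
`envelope ∪ cavity` by default, so deep sampling windows that reach the
medullary cavity report its void toward porosity — this is the mechanism by
which measured porosity climbs toward 80–100% in the deep cortex near the
bone ends, where the thin wall lets windows cross the endosteum.
`include_cavity = FALSE` restricts the measurement to intracortical void
only.

### Canal diameter: discrete local thickness

Per-voxel canal diameter is the maximal-inscribed-sphere local thickness of
the void phase: at voxel *x*, the diameter of the largest sphere lying
entirely in the void and containing *x*. The implementation computes the
exact squared Euclidean distance transform (Felzenszwalb–Huttenlocher,
separable, exact integers in voxel units), reduces sphere centres to the
distance ridge (spheres provably contained in a neighbour's sphere are
skipped — an exact reduction), and paints each remaining sphere over the
voxels it strictly contains. The result is identical, voxel for voxel, to an
exhaustive oracle that tests the sphere centred at every void voxel; the
test suite asserts this on randomized masks up to 32³.

Committed conventions:

- *Sphere radius* is the centre-to-centre distance to the nearest background
  voxel, with strict `<` membership. An isolated single void voxel therefore
  has thickness 2 × voxel size, and every positive thickness is at least
  that. This convention overstates the geometric diameter of small digitized
  structures by up to ~1 voxel; for the default 5.8 µm voxels and canals of
  40 µm and up the bias is below ~10% and shrinks with canal size.
- *Array boundaries*: transverse (y, x) faces are exterior (background);
  longitudinal z faces are open, i.e. canals are assumed to continue beyond
  the imaged extent. A full-length canal thus carries no end artifact.
- *Which void counts*: diameter statistics are computed on the
  "intracortical void" phase — void components (2D, 8-connected, per slice)
  that touch non-envelope space are excluded, because they are either
  closing-boundary residue or void continuous with the cavity/exterior, not
  canals. Porosity is unaffected by this exclusion.

The per-ROI "mean canal diameter" is volume-weighted (every void voxel
contributes equally), matching the volume-percentage framing of the
canal-diameter histograms; since canal volume scales with d², two
equal-length canals of 40 and 80 µm yield a weighted mean of 72 µm and land
in histogram bins [25, 50) and [75, 100) in a 1:4 volume ratio — both are
regression-tested. Histogram bins default to 0–375 µm in 25 µm steps,
right-open except the last; percentages sum to 100 exactly.

### The ROI scheme

Sampling follows the standard radial/longitudinal scheme: transverse slabs at
1 mm intervals from the distal end (z = 0), each position aggregating a full
step of slices (single-plane mode available); on each slab's central slice,
rays run from the envelope centroid along the four image axes, labelled
anterior (+y), posterior (−y), medial (−x), lateral (+x). The anatomical
labels are a declared image-axis convention recorded in the outputs — true
anatomical registration is out of scope. The periosteal surface point is the
outermost envelope voxel on the ray (ray casting against the envelope, not
the raw mask, so surface pores cannot produce false early hits).

Each window is 500 µm tangential × 250 µm radial. Depth *d* anchors the
window's *inner* edge: the window spans the radial band [d − 250 µm, d], so
the first sample (d = 250) covers the periosteal 0–250 µm band. The
tangential extent is rasterized symmetrically (an odd voxel count centred on
the ray), which makes direction-averaged profiles exactly invariant under
on-grid 90° rotations of the volume — a property the tests assert. Sampling
continues inward until a window contains no envelope voxels, at which point
placement returns an invalid ROI with its reason, and all downstream tables
propagate `NA` without aborting.

Cortical thickness along a ray is the chord of the contiguous envelope run
containing the surface point — periosteum to endosteum. On solid sections
with no cavity along the ray the full chord from the centroid is returned
and flagged `no_cavity`.

### Two-regime modulus extraction

Compression records (displacement mm, force N) convert to engineering
stress–strain via σ = F/A and ε = δ/t, origin-shifted so the first sample is
(0, 0); t is the nominal 2.0 mm slice thickness and A the loaded area, which
must be supplied per specimen. The "two distinct linear regions" are
operationalized as a *continuous* two-segment piecewise-linear least-squares
fit: for each candidate breakpoint on an interior grid of the pre-peak
strains (excluding the first and last 10% of points so both segments retain
support), the three-parameter basis (intercept, ε, (ε − b)₊) is fitted and
the breakpoint minimizing total squared error is selected; the optimum is
then refined continuously within its bracketing grid interval. Ties are
broken toward the smaller breakpoint strain, so a perfectly straight line
returns the smallest candidate with both slopes equal. The fit domain ends
at the peak-stress index; post-peak softening never contaminates the slopes.
Maximum compressive strength is the sample maximum of stress. No toe-region
trim is applied by default (no preload is assumed); `min_strain` provides an
optional cut. Noiseless generated curves are recovered to 1 × 10⁻⁶ relative
in both slopes; at 1% stress noise the median slope error stays below 5%
(both tested).

### Pairing and correlation

Structural and mechanical records pair by nearest longitudinal position
within a tolerance (default 0.5 mm); equal-distance ties go to the smaller
position, and unmatched records are reported, never silently dropped.
Correlations are Pearson product-moment with two-tailed p-values from the t
statistic r·√((n−2)/(1−r²)) on n − 2 degrees of freedom (delegated to
`stats::cor.test` and verified against a quadrature oracle of the t density
to 1 × 10⁻⁸). Both pooled and per-replicate analyses are emitted; no
multiple-testing correction is applied by default (a Holm option exists),
and a Spearman variant is available as an extension for the visibly
non-linear porosity–modulus relation.

## The synthetic phantom: what it emulates

No real specimen ships with voxel-level ground truth, so validation rests on
a generator whose truth is exact by construction. The phantom is a hollow
shell: fixed outer radius (default 1000 µm), wall thickness varying
quadratically from 400 µm at both ends to 650 µm at mid-shaft, length 4 mm,
voxel 5.8 µm — a deliberately scaled-down diaphysis chosen so the full
pipeline runs in minutes on one CPU; the geometry, not the physics, is
reduced. Canals are straight cylinders parallel to the long axis (the
dominant orientation of Haversian canals in shaft cortex), placed by
rejection sampling of non-overlapping disks inside (longitudinal band ×
radial ring) cells:

- The **axial porosity profile** runs from 5% (mid-shaft) to 40% (ends),
  quadratically; a **radial factor** (0.7 at the surface to 1.3 at the
  endosteum) superimposes the through-wall gradient. Mean canal diameter
  runs 40 µm (shaft) to 110 µm (ends) with a 0.85–1.15 radial factor;
  individual diameters are log-normal with CV 0.25 (strictly positive and
  right-skewed, like observed canal-size histograms).
- **Packing feasibility**: non-overlapping disks jam well below dense
  packing, so per-cell targets are capped at 0.45·(1 − D/W), where D is the
  cell's mean diameter and W its ring width; the effective targets are
  recorded in the returned ground truth, and the placement invariant
  (realized void fraction within 2 percentage points of the effective
  target, per cell) is tested. With the cap disabled an unreachable target
  aborts, naming the band and ring. The measured porosity near the bone ends
  still reaches ~40–100% because the thin end wall lets deep windows reach
  the cavity — the same mechanism as in real bone — so the cap does not
  flatten the measured gradient.
- **Exactness engineering**: canal centres snap to voxel centres (making
  the discrete inscribed-sphere diameter an essentially unbiased estimate of
  the true canal diameter), and canals keep two voxels of clearance from
  each other, the cavity, and the periosteal surface, so no sub-voxel bone
  sliver can arise that despeckling would remove: thresholding a noise-free
  phantom reproduces its truth labels *exactly*, and the total void volume
  equals the sum of per-canal voxel counts *exactly*. A voxel is void iff
  its centre lies inside a canal; bone renders at intensity 200, void at 20
  (straddling the threshold 80 with margin), with optional Gaussian
  intensity noise (0 in tests, 10 in demos).
- Longitudinal placement bands default to 1000 µm, matching the 1 mm
  sampling grid; canals dead-end at band boundaries, which depresses the
  thickness map within about a canal radius of each boundary — with 1 mm
  bands this contributes at most a few percent to volume-weighted ROI means.

`true_profile()` computes exact per-window truth from the label volume by
voxel counting, with diameters taken from the canal records
volume-weighted by in-window voxel count, using the *same* resolved windows
as the measurement pipeline so discretization cancels from the comparison.

What the phantom does **not** emulate: oblique, branching or anastomosing
canals; osteonal lamellae and cement lines; trabecular rod–plate
architecture at the metaphyses (the high end-porosity here comes from the
cavity, not from trabecular structure); scanner physics (beam hardening,
ring artifacts, partial-volume blur — intensities are bimodal by
construction); lacunar porosity below micro-CT resolution. Passing the
recovery tests therefore demonstrates that the *measurement chain* is
correct and unbiased on geometry it can represent — not that segmentation at
threshold 80 is optimal for any particular scanner's reconstruction.

## Validation summary (all computed by the test suite)

- Local thickness ≡ exhaustive sphere oracle, voxel-for-voxel, on randomized
  masks up to 32³; digitized cylinder of radius 8 voxels reads 16 ± 1.
- ROI porosity ≡ brute-force voxel counting, exactly, on random phantoms.
- Noise-free segmentation closure: threshold ∘ despeckle reproduces truth
  labels exactly; despeckle is idempotent and subset-monotone.
- Default graded phantom: recovered porosity within 2 percentage points of
  truth at every (position, direction, depth); volume-weighted mean diameter
  within 10% wherever canals are sampled; longitudinal porosity minimum at
  mid-shaft; deeper windows at least as porous as shallow ones.
- Bilinear fit: noiseless recovery to 1e-6; median slope error ≤ 5% at 1%
  noise; scale-equivariant; never worse than the single-line fit.
- End-to-end demo study: negative porosity–modulus and diameter–modulus
  correlations, modulus peak co-located with the thickness peak, and
  byte-identical outputs across reruns at a fixed seed.

## Known limitations

- Direction labels are image-axis conventions; comparing directional
  profiles across specimens requires consistent mounting or an external
  rotation, which the package accepts but does not infer.
- The discrete thickness convention overstates diameters of structures only
  a few voxels wide; at 5.8 µm voxels, canals below ~25 µm should not be
  interpreted quantitatively.
- Cortical thickness is a ray chord through the centroid; for strongly
  non-convex sections a minimum-distance definition would differ.
- The bilinear fit assumes exactly two regimes before the peak; records with
  a pronounced toe region need `min_strain`, and genuinely nonlinear
  pre-peak behaviour will be averaged into the two slopes.
- The load area is the caller's responsibility (apparent vs net bone area is
  a real ambiguity in slice testing); moduli scale inversely with it.
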