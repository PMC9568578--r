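---
title: "3D muscle fiber population analysis: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{3D muscle fiber population analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

High-resolution X-ray tomography of skeletal muscle biopsies produces 3D
grayscale volumes in which hundreds of individual muscle fibers — bright,
roughly parallel tubes of 30–100 µm diameter — can be followed over their
whole length. Classical 2D histology sees only cross-sections; in 3D one can
additionally quantify each fiber's *trajectory*, which turns out to carry
disease signal: atrophic muscle shows tortuous, buckling, splitting, and
broken fibers that a single 2D slice misreads as several neighboring
profiles. `fibertube` implements the full analysis chain from such a volume
to per-fiber morphometry and population statistics, together with a
synthetic phantom generator that provides analytic ground truth for every
stage.

## The processing model

The pipeline mirrors how tubular structures are segmented in the
optimal-surface literature:

1. **Seed masks to centerlines.** Each fiber is identified by an
   integer-labeled seed mask (in practice a thin painted track through the
   fiber's core; a full tube mask works too). The mask is thinned with a
   topology-preserving 3D algorithm (26-connectivity foreground,
   6-connectivity background, curve endpoints kept), the longest branch-free
   path through the skeleton graph is extracted (exact on trees via two
   shortest-path sweeps; exhaustive search for small cyclic skeletons), the
   path tips are grown back along the mask to undo thinning's end recession,
   and the result is resampled at equal arc-length steps (default: the voxel
   size, 1.32 µm at the reference resolution) and lightly smoothed to remove
   voxel staircase jitter.

2. **Centerlines to surfaces.** Around each centerline point an orthogonal
   sampling plane is defined using rotation-minimizing (parallel-transport)
   frames — Frenet frames would spin at inflection points of wavy fibers.
   Voxel intensities are sampled along radial spokes (default 60 spokes at
   6°, reaching 140 µm with 3.2 µm radial steps; for small-fiber phantoms we
   set the spoke length to the largest expected radius plus a safety margin
   and the radial step to the voxel size, which localizes the boundary more
   precisely at negligible cost). Since fibers are the brightest structures,
   the outer border is modeled as the strongest negative radial intensity
   gradient (second-order central differences). The boundary radius
   `r(slice, spoke)` is found as the *globally* optimal surface through this
   cost terrain subject to hard smoothness bounds (default: ≤ 2 radial
   samples between adjacent spokes, circularly; ≤ 1 between adjacent
   slices), solved exactly as a minimum s–t cut on the standard
   optimal-net-surface graph. A minimum radius of 2 samples forbids collapse
   onto the centerline. The detected radius is then localized to sub-sample
   precision by parabolic interpolation of the cost profile.

3. **Refinement.** Each centerline point is moved to the area centroid of
   its detected cross-sectional polygon, smoothed, and the surface is
   re-detected (one refinement pass by default). The terminal slices have
   one-sided tangents and often touch the volume faces, so they inherit the
   displacement of the nearest interior slice instead of trusting their own
   centroids, and the volume is reflection-padded along z before
   segmentation so spoke planes near the faces sample plausible data. Both
   measures remove an end-instability that otherwise inflates the measured
   tortuosity of straight fibers severalfold.

4. **Rasterization without overlaps.** A voxel belongs to a fiber when its
   in-plane radius relative to the nearest centerline point is below the
   angularly interpolated boundary radius. Voxels claimed by several fibers
   go to the fiber whose boundary they are deepest inside (largest radius
   margin; ties to the nearest centerline), so the output labels are
   disjoint by construction — mirroring the biological constraint that
   fibers do not interpenetrate.

## Morphometry

Per fiber, from the refined centerline `p_1..p_N`:

* length `d = Σ ||p_{i+1} − p_i||` (summed Euclidean distances), and
* sinuosity `s = d / ||p_N − p_1||`, which is 1 for a straight fiber and
  grows with tortuosity. Closed loops (coincident endpoints) have undefined
  sinuosity and are reported separately.

Per cross-section, sampled every 9.2 µm of arc (about every 7th slice at the
reference resolution): the segmentation mask is cut orthogonally to the
local direction, the outer boundary of the largest connected component is
fitted with a direct least-squares ellipse (numerically stable partitioned
formulation; a second-moment fallback handles degenerate fits and is
logged). Boundary pixel centers lie about half a pixel inside the true
boundary, so they are pushed half a pixel outward radially before fitting —
at 16-voxel fiber diameters this removes a 6% size bias. With semi-axes
`a ≥ b` the ellipse area is `A = πab`, the equivalent circle diameter
`ø = 2√(A/π)` (the local thickness proxy), and the eccentricity
`e = √(1 − b²/a²)` (0 = circular). We interpret the fitted "axis lengths" as
semi-axes; `e` is invariant to that choice and `ø` is validated against
ground truth in the tests. Only the cylindrical, fully illuminated part of
the field of view is trusted: any section whose mask crosses the inscribed
cylinder wall or touches the top/bottom slice is discarded.

Fiber length and sinuosity are measured from the refined, smoothed
centerline; empirically this estimator is unbiased to within ~0.5% of
sinuosity on phantoms, with a mild attenuation of very short-wavelength
wiggle from the smoothing window (5 points).

Population statistics: muscle volume fraction (percentage of voxels with a
fiber label, optionally within the FOV cylinder), median/IQR summaries with
linear-interpolation quartiles (type 7) and boxplot whiskers at 1.5 IQR
truncated at the extrema, Gaussian kernel density estimates with Silverman's
bandwidth, two-sided Wilcoxon rank-sum tests (exact for small untied
samples), the Brown–Forsythe test (one-way ANOVA F on absolute deviations
from group medians), and Pearson correlation between diameter and
eccentricity. Cross-sections are pooled as observations by default,
replicating how such population analyses are usually reported; a
fiber-level aggregation mode (`fiber_level = TRUE` in `compare_groups()`) is
available as a robustness option.

## The phantom generator

Because raw tomography volumes of this kind are rarely deposited, every
stage is validated against synthetic phantoms with analytic ground truth
(`phantom_spec()`, `generate_phantom()`). The generator emulates what the
pipeline must cope with, not the imaging physics:

* **Geometry.** Fibers span the z extent of the grid. Transverse positions
  come from deterministic bottom-left first-fit disc packing, where each
  fiber reserves its maximum radius plus its bending amplitude — so
  heterogeneous diameters pack densely without systematically rejecting
  large fibers — followed by a centered expansion toward the target packing
  fraction. Bending is the sum of a coherent field shared by all fibers
  (packed fibers bend together; amplitude set by `shared_frac` of the median
  sinuosity excess) and a per-fiber short-wavelength sinusoid (5–7
  half-periods) whose amplitude is solved numerically so the analytic
  sinuosity matches a per-fiber target drawn from the stated median/IQR.
  Both components vanish at the fiber ends, keeping the chord equal to the
  grid height. Hard no-overlap is enforced by a surface-to-surface collision
  check with redraw-and-damp retries; unplaceable fibers are reported, and
  the generator errors when the achieved packing falls below half its
  target.
* **Cross-sections** are ellipses of specified eccentricity and random
  orientation; diameters are truncated-normal draws matching a median/IQR.
* **Pathology phenotypes.** `buckle` inserts a localized helical fold-back
  loop (z becomes non-monotone, so a single 2D slice shows ≥ 2 disconnected
  profiles of the same fiber — the "visible in 3D, invisible in 2D"
  phenomenon); `split` adds a branch sharing the trunk, with both branches
  shrinking past the split point; `break` removes a mid-fiber window,
  leaving two disjoint segments under one label; `swell` inflates the radius
  profile locally by 45%. Loops and branches point toward the domain center
  and displace their neighbors through the collision check, emulating focal
  lesions.
* **Intensity model.** Two levels (fiber 100, background 20), Gaussian
  partial-volume blur (default 1 voxel), then additive Gaussian noise. The
  tomographic contrast of unstained tissue is weak and unspecified; this
  two-level stand-in tests boundary detection, not reconstruction physics.

What the phantoms deliberately do **not** emulate: phase-contrast fringes,
ring artifacts, the degraded periphery of a real reconstruction (the FOV
filter handles that geometry instead), polygonal deformation of tightly
packed fibers (our tubes are stiff, so achievable packing tops out near 55%
rather than the ~75% of real tissue — the three presets therefore use 52 /
36 / 20% to preserve the dense / dense / sparse contrast), and intramuscular
connective tissue. Passing tests on phantoms show the *analysis* is
faithful; they do not certify performance on real acquisitions with unknown
contrast.

## The three-condition study

`phantom_preset()` provides scaled-down populations emulating a healthy
control (thick, straight, densely packed: diameter median;IQR 37.2;5.2 µm —
half the biological scale so that ~120 fibers fit in a desk-scale grid —
sinuosity 1.02;0.02, eccentricity 0.54), an atrophic sample (thinner
25.1;9.2 µm, broader sinuosity 1.06;0.09, 6% buckling), and a severely
atrophic sample (sparse, mixed 35.6;14.4 µm with swelling, splits and
breaks, sinuosity 1.12;0.11, eccentricity 0.43). Group sizes (120 / 132 / 34
requested fibers on 328² / 276² / 336² × 64 grids at 1.6 µm voxels) were
chosen by power analysis so that, at these effect sizes, both the Wilcoxon
and Brown–Forsythe tests on per-fiber sinuosity can reject at p < 0.001 —
the Brown–Forsythe test in particular needs on the order of a hundred
fibers per dense group
because buckled outliers inflate the within-group variance of the absolute
deviations. `run_study()` reproduces the reference directionality: median
diameter atrophic < healthy, sinuosity healthy < atrophic < severe, volume
fraction severe ≪ the dense groups, and all four sinuosity tests rejecting
at p < 0.001.

## Numerical choices and edge cases

* Voxel `(i, j, k)` (1-based) has its center at `(i−0.5, j−0.5, k−0.5) ×
  voxel_size`; all geometry is in micrometers, voxels appear only at
  rasterization and I/O. Only isotropic voxels are supported.
* Downsampling (`downsample()`, factor 4 for raw 0.33 µm acquisitions)
  interpolates trilinearly at the *new voxel centers*, clamped within half a
  voxel of the faces; the phase convention is fixed and tested against the
  closed-form interpolant.
* Spoke samples outside the grid are invalid (+Inf cost); columns with no
  valid sample get a uniform cost so the smoothness constraints alone set
  their radius.
* Ties in the longest-path search break toward the lexicographically
  smallest endpoint; large cyclic skeletons (rare; buckle loops) fall back
  to the two-sweep heuristic with a warning.
* Broken fibers produce separate records sharing a parent id
  (`"<label>.<k>"`); empty cross-sections across a gap are recorded as
  missing, never fabricated. Gaps are reported, not auto-merged: the
  decision that two fragments are one fiber is left to the analyst.
* Degenerate inputs error early with descriptive messages: anisotropic NRRD
  spacings, TIFF without a voxel size, sub-6-point or collinear ellipse
  boundaries, closed-loop sinuosity, empty masks and ROIs.

## Problem sizes used in the validation suite

The shipped tests exercise the full pipeline on a 144×144×96 recovery
phantom with 10 fibers (noise-free and at 10%-of-contrast noise) and on the
three-preset study above; oracle equivalences run on small random instances
where exhaustive enumeration is feasible (surface terrains with ≤ 10^5
feasible configurations, skeletons of ≤ 15 voxels). These sizes were chosen
so the whole suite completes in well under half an hour on a single CPU
while still covering every stage end to end.

## Known limitations

* The no-overlap rule is enforced at rasterization; a joint multi-surface
  optimization of touching fibers would be the principled extension.
* Measured sinuosity carries a small positive noise floor (~1.01 for
  perfectly straight fibers at 1.6 µm voxels), consistent with the
  practical floor noted for this kind of analysis.
* The smoothing that stabilizes length estimates slightly attenuates
  sub-20-µm wavelength wiggle; group contrasts are preserved.
* Brown–Forsythe on heavy-tailed sinuosity distributions is conservative;
  rejections at small group sizes require large spread ratios.
* The generator draws cross-sectional eccentricity independently of
  diameter, so the weak negative diameter–shape correlation seen in real
  muscle tissue is not emulated; the reported Pearson r on phantoms mainly
  reflects measurement coupling at small fiber sizes.
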