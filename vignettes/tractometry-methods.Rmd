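---
title: "Methods: lesion tractometry with robust shift functions and along-tract profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lesion tractometry with robust shift functions and along-tract profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its models, parameters,
numerical choices and limitations. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The analysis model

A unilateral brain lesion (tumor plus peritumoral signal change) alters
water diffusion in the white matter it infiltrates: fractional anisotropy
(FA) falls; mean, axial and radial diffusivity (MD, AD, RD) rise. The
package quantifies this at three spatial scales, always using the
patient's contralesional hemisphere as the within-subject control:

1. **Hemisphere scale.** All tract voxels of the ipsi- and contralesional
   hemispheres are compared as whole distributions via the decile shift
   function, plus a downsampled Wilcoxon rank-sum test and the normalized
   hemispheric difference `100 (D_I - D_C) / D_avg`, which is correlated
   with percent tumor volume.
2. **Bundle scale.** A targeted bundle (e.g. a corticospinal-tract
   analog) is split by ROI/ROA recipes into contralesional (C),
   lesion-avoiding (IE) and lesion-crossing (II) track groups, whose mean
   coefficients are compared by Kruskal-Wallis with Dunn post-hoc tests.
3. **Node scale.** Tracks are resampled to a common node count and their
   coefficient values, normalized to the contralesional mean, are
   profiled against the signed distance of each node from the lesion
   boundary.

## Tracking

The tracker propagates streamlines bidirectionally through a single
principal-direction field, one direction per voxel. At each 1 mm step the
field vector at the current position (nearest voxel; trilinear optional)
is sign-aligned with the incoming direction; propagation terminates if it
turns more than the 55 degree angular threshold, if FA at the candidate
position is below 0.15, if the field vanishes, or if the track leaves the
grid. The accepted direction is smoothed as
`normalize(0.5 raw + 0.5 previous)` (the smoothing fraction weights the
previous direction), and tracks outside 30-300 mm arc length are
discarded; 50,000 seeds are placed uniformly at random inside the seed
mask with random sub-voxel positions. The angular gate is applied to the
raw field orientation rather than to the smoothed direction — smoothing
can only shrink the turning angle, so gating the smoothed direction would
let a field that bends 90 degrees pass a 55 degree threshold.

This is deliberately a single-fiber tracker: it exercises every stated
tracking parameter on phantom data but does not resolve crossing fibers.
Real-data users can import externally tracked TRK/TCK files into the same
pipeline (`analyze_subject(..., tracks = read_streamlines(...))`).

## Geometry conventions

World coordinates are RAS mm; the affine maps zero-based voxel indices to
world coordinates as in the NIfTI header, and R-facing functions use
1-based indices. A world point at a voxel's center has a continuous voxel
coordinate equal to that voxel's integer index, and a point belongs to
the voxel given by the floor of its continuous coordinate. TRK files
store voxel-scaled, corner-origin coordinates; they are converted to
world mm on read and back on write (verified in the tests against an
independent neuroimaging reader). Streamline-mask intersection densifies
each polyline to steps of half the smallest voxel size, so a segment
cannot jump a one-voxel-thick mask — necessary when 1 mm steps meet
2.6 mm slices.

## Harrell-Davis shift function

The Harrell-Davis estimator of quantile `q` is the beta-weighted sum of
all order statistics (weights `I(i/n; a, b) - I((i-1)/n; a, b)`,
`a = (n+1)q`, `b = (n+1)(1-q)`). The shift function reports the nine
decile differences between two samples with bootstrap confidence
intervals: 100 iterations, 200 observations resampled with replacement
per group per iteration.

Two numerical choices matter here:

- A bootstrap at resample size `m` estimates the variance of an
  `m`-observation statistic. When `m` differs from the group size `n`,
  each group's bootstrap variance is rescaled by `m / n` before the
  per-group variances are summed (the groups are independent). Without
  this, a fixed `m = 200` on `n = 500` samples would overstate the SE by
  `sqrt(500/200)` and the intervals would be far too wide. Resampling at
  full size is available (`samples_per_iteration = NULL`).
- Intervals use the t critical value at the bootstrap degrees of freedom
  (`2 (B - 1)`) rather than z, because the SE is itself estimated from
  `B = 100` replicates. The suite's calibration test (two samples from
  the same normal, n = 500, 200 Monte-Carlo replications) verifies the
  per-decile false-positive rate stays in the 99% binomial band around
  the nominal 5%; a residual inflation of roughly one percentage point is
  intrinsic to normal-theory intervals built on a noisy bootstrap SE at
  B = 100.

The downsampled Wilcoxon test reduces each tract-voxel distribution by a
factor of 50 (random subsampling without replacement) before a two-sided
tie-corrected normal-approximation rank-sum test: voxelwise values along
a tract are heavily spatially autocorrelated, and the subsampling keeps
the effective sample honest. Both samples are subsampled from the same
seeded stream so that swapping the arguments selects identical subsets
and exactly negates Z.

## Group comparison: the unit of analysis

Streamlines within one subject share anatomy, noise and selection, so
treating per-streamline means as independent observations would
pseudoreplicate massively (thousands of "observations" from 13 actual
subjects) and declare microscopic differences significant. The default
unit for the Kruskal-Wallis/Dunn comparison of C/IE/II is therefore the
**per-subject mean** of min-max-normalized per-streamline means (13
values per group); per-streamline and per-voxel units are available for
exploration. Min-max normalization is applied per subject and coefficient
across all groups jointly, so groups remain comparable within a subject.
Dunn z statistics use pooled tie-corrected ranks and are gated on the
omnibus test at p < 0.05; p-value adjustment across pairs is configurable
(none by default).

## Along-tract profiles

The common node count is the rounded mean point count over all tracts of
a group across subjects. Resampling fits a natural cubic spline through
the points parameterized by cumulative chord length, evaluates it densely
and re-interpolates at uniform arc length, preserving endpoints exactly
and recovering a quarter-circle's arc length to better than 0.1% (tested).
Node values are sampled nearest-voxel by default: with a sharp-edged
phantom (zero-FA background), trilinear interpolation blends bundle-edge
nodes with the background and biases edge-hugging track groups; nearest
sampling matches the voxel-set extraction used everywhere else. Trilinear
sampling remains available for smooth real data.

Signed distances are exact minimum Euclidean distances (anisotropy-aware,
in mm) from each node to the nearest lesion boundary-voxel center,
negative inside the lesion; boundary voxels are mask voxels with a
non-mask face neighbor. The contralesional group is measured against the
lesion mirrored across the midsagittal plane (taken as the grid's center
plane along the chosen axis), an exact, volume-preserving involution.

Binned profiles (2 mm bins by default; the bin width is not dictated by
the method and 2 mm matches the phantom voxel size) summarize each
(bin, group) cell as mean and 95% t-interval. The default CI unit is the
**per-subject bin mean** — the same pseudoreplication argument as above:
pooled node values within a bin are dominated by repeated visits to the
same voxels, and their nominal CIs shrink with a fictitious n. Bins with
fewer than three values are flagged `low_n` and excluded from CI-overlap
flags, since an interval from one or two subjects is degenerate (zero
width or a t quantile at one degree of freedom). Far-distance bins hold
few nodes and are expected to be noisy.

## The phantom: what it emulates and what it does not

`phantom_spec()` defines a two-hemisphere grid (60 x 72 x 60 voxels at
2 mm) with one arched, mirror-symmetric fiber bundle per hemisphere
(circular-cross-section tubes of radius 8 mm around a spline centerline,
about 135 mm long) and an ellipsoidal lesion placed laterally across part
of the ipsilesional bundle, so that lesion-crossing and lesion-avoiding
tracks both exist — as in a tumor abutting a motor bundle. Healthy tissue
has FA 0.7 inside bundles (zero-FA background, so the direction field is
unit norm wherever FA > 0), MD 8e-4, AD 1.4e-3, RD 5e-4 mm^2/s. The
lesion lowers FA by 0.2 and raises the diffusivities by 3e-4 mm^2/s at
full strength, decaying exponentially outside the lesion with a 2 mm
e-folding length: the injected damage is confined to the lesion and its
immediate neighborhood, which is the qualitative structure the analysis
is designed to recover. Distances for the injected effect use the scaled
radial ellipsoid distance (exact for spheres), independent of the
along-tract module's mask-based distance code.

Additive Gaussian noise is specified separately for FA (sd 0.04) and the
diffusivities (sd 6e-5) — one additive sd cannot fit quantities three
orders of magnitude apart — giving an effect-to-noise ratio of 5 for both
FA and MD. Noise is drawn from per-hemisphere, per-map substreams, and
the injected effect is confined to the ipsilesional hemisphere, so
contralesional data are bit-identical across lesion settings for a fixed
seed (tested).

`phantom_cohort()` emulates a retrospective clinical series: 13 subjects,
lesion radii scaled by 0.7-1.25, center jittered by a few mm, sides
alternating, baseline FA/MD varying slightly across subjects, and a small
per-subject hemispheric baseline asymmetry (relative right-left
difference, sd 0.003) of the kind seen physiologically. The asymmetry
magnitude was fixed once, at design time, by simulating cohorts across
several seeds so that the generator reproduces the qualitative study
conditions — lesion-crossing tracks clearly abnormal, lesion-avoiding
tracks statistically indistinguishable from the control bundle, and
unanimous signs of the hemispheric FA/MD differences — with comfortable
margins on all three at once.

What the phantom does **not** emulate: crossing or kissing fibers,
partial-volume gradients at tissue interfaces, realistic cortical
anatomy, multi-lesion or midline-crossing tumors, registration error, or
physiologic noise structure (noise here is i.i.d. Gaussian). Passing
tests therefore show the pipeline's statistics and geometry are correct
and that it recovers known injected effects at clinical effect sizes —
not that any particular clinical dataset will show those effects.

## Other design choices

- ROI semantics are AND across ROIs and NOT-ANY across ROAs; a recipe
  whose ROI lies entirely inside the ROA union is rejected at
  construction.
- Tract-voxel extraction deduplicates voxels by default ("tract voxels"
  as a set, not a visit multiset); per-visit counting is available.
- `D_avg` in the normalized hemispheric difference is the mean over both
  hemispheres' tract values pooled.
- Brain volume for percent tumor volume is an input scalar; the phantom
  supplies its ground-truth grid volume.
- Problem sizes in the tests: unit tests run on a 40 x 48 x 40 phantom
  with a few thousand seeds; the acceptance suite runs the full default
  phantom (50,000 seeds) and a 13-subject cohort, chosen to exercise the
  study-scale conditions while keeping a complete run to a few minutes.
- Volumes whose NIfTI affine is non-invertible are rejected on read;
  constant inputs to min-max normalization and zero-variance inputs to
  the correlation are errors, not silent NaNs; degenerate (constant)
  samples give exact zero-width shift-function intervals.

## Known limitations

- The tracker follows one direction per voxel; in crossing-fiber regions
  of real data an external tracker should be used upstream.
- With lesions of varying size and a fixed injected effect, the
  normalized hemispheric difference grows with lesion size by
  construction, so the volume-diffusion correlation is strongly negative
  for FA on the default cohort; the no-effect cohort (delta = 0)
  recovers a null correlation, and that is the configuration under which
  a flat volume-effect relationship should be interpreted.
- TRK voxel-order handling assumes the header's voxel order is consistent
  with its voxel-to-RAS matrix (true for files this package writes and
  for standard tools).
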