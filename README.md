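# tractshift

Tractometry of lesion impact on white matter: robust hemispheric shift
functions, ROI/ROA streamline group comparisons, and along-tract profiles
of diffusion coefficients by distance from the lesion boundary.

## The problem

Gliomas infiltrate the white matter around them. Diffusion MRI tractometry
asks *where* and *how much* the tumor degrades fiber-bundle
microstructure: fractional anisotropy (FA) falls and mean/axial/radial
diffusivity (MD/AD/RD) rise in damaged tissue. Because patients differ,
the healthy contralesional hemisphere serves as the within-subject
control. This package implements that analysis end to end for
neuroimaging researchers:

- **Tracking** — a deterministic streamline tracker on a principal
  fiber-direction field, with the standard clinical gates: FA threshold
  0.15, angular threshold 55°, 1 mm steps, 50% direction smoothing,
  30–300 mm length window, 50,000 random seeds. Externally tracked
  TRK/TCK files can be imported instead.
- **Selection** — ROI/ROA recipes split tracks into the analysis groups:
  contralesional (C), ipsilesional (I), lesion-avoiding (IE) and
  lesion-crossing (II).
- **Robust hemispheric comparison** — the decile *shift function*:
  Harrell–Davis estimates of the deciles of the ipsi- and contralesional
  coefficient distributions, with bootstrap confidence intervals
  (100 iterations × 200 resamples) on each decile difference, plus a
  downsampled (×50) Wilcoxon rank-sum test. The Harrell–Davis estimate of
  quantile *q* from order statistics `x(1) <= ... <= x(n)` is

  `hd(q) = sum_i [ I(i/n; a, b) − I((i−1)/n; a, b) ] x(i)`,
  with `a = (n+1)q`, `b = (n+1)(1−q)` and `I` the regularized incomplete
  beta function.
- **Volumetry** — lesion volume by voxel counting, percent tumor volume,
  and the normalized hemispheric difference
  `100 · (D_I − D_C) / D_avg` per coefficient, correlated with tumor
  load (Pearson).
- **Along-tract analysis** — streamlines resampled by spline to a common
  node count, coefficients normalized to the contralesional-hemisphere
  mean, each node assigned its signed Euclidean distance to the lesion
  boundary (negative inside), and group profiles binned by distance with
  95% CIs and CI-overlap flags. The control group is measured against the
  lesion mirrored onto the healthy hemisphere.
- **Synthetic phantoms** — a generator with full ground truth (arched
  fiber bundles, unilateral ellipsoidal lesion, exponentially decaying
  effect, calibrated noise) validates every stage at cohort scale.

## Worked example

```r
library(tractshift)

# a 13-subject synthetic cohort: unilateral lesions, delta FA = -0.2,
# delta MD = +3e-4 mm^2/s inside the lesion, decaying over 2 mm
cohort <- phantom_cohort(13, rng_seed = 1)
an <- run_cohort_analysis(cohort, rng_seed = 1)
an
#> <cohort_analysis> 13 subjects (0 excluded)
#> Kruskal-Wallis + Dunn (per-subject values):
#>   FA : H(2) = 27.59, p = 1.02e-06
#>   MD : H(2) = 27.24, p = 1.22e-06

tidy(an$group_tests$fa)
#> # A tibble: 3 x 6
#>   group1 group2     z      p.value   p.adjusted gated
#>   <chr>  <chr>  <dbl>        <dbl>        <dbl> <lgl>
#> 1 C      IE      1.50 0.135        0.135        FALSE
#> 2 C      II      5.11 0.000000325  0.000000325  FALSE
#> 3 IE     II      3.61 0.000304     0.000304     FALSE
```

Reading: tracks that *cross* the lesion (II) have significantly lower FA
than both the contralesional control (C) and the lesion-avoiding tracks
(IE), while IE and C are statistically indistinguishable — damage is
confined to the lesion and its immediate vicinity. The along-tract
profiles localize this: `an$overlap_flags` marks non-overlapping 95% CIs
for II vs C in 100% of the distance bins inside the lesion and in almost
none of the bins beyond three decay lengths. Per subject, the normalized
hemispheric FA difference (Eq. above) is negative and the MD difference
positive — e.g. a mean FA difference of about −2.5% across this cohort.

`write_analysis(an, "out/")` writes every table as TSV plus a JSON
manifest; `autoplot()` methods plot shift functions, mirrored densities
and binned profiles.

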