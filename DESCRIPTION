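Package: tractshift
Title: Tractometry of Glioma Impact on White Matter with Robust Shift
    Functions and Along-Tract Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies how a unilateral brain lesion alters white-matter
    diffusion properties. Provides deterministic streamline tracking on a
    principal-direction field with fractional-anisotropy, angle and length
    gates; ROI/ROA streamline selection into contralesional, ipsilesional,
    lesion-avoiding and lesion-crossing groups; robust hemispheric comparison
    of diffusion-coefficient distributions via the Harrell-Davis decile shift
    function with bootstrap confidence intervals and a downsampled Wilcoxon
    rank-sum test; tumor volumetry with normalized hemispheric diffusion
    differences; and a group-level along-tract analysis that localizes
    diffusion changes by signed distance from the lesion boundary. A synthetic
    phantom generator with known ground truth supports end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
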