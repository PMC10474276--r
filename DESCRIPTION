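Package: rcmorph
Title: Rotator Cuff Morphometry from Partial-Coverage Shoulder Label Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Objective three-dimensional quantification of rotator-cuff muscle
    size, relative contribution, and fatty infiltration from partial-coverage
    shoulder segmentation label maps. Predicts total scapula length from
    lateral scapular morphology via a multivariable linear regression, builds
    location-normalized cumulative volume curves on a one-percent grid of the
    scapula, rigidly registers full-coverage label maps to partial ones,
    compares partial- to full-coverage metrics, analyses sex and age effects
    with two-way ANOVA, and supports a normative reference database with
    demographic z-scoring. Includes a synthetic shoulder phantom generator
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    car,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
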