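Package: junctionzone
Title: Contour-Line Analysis of Photoreceptor Thinning Around Geographic Atrophy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify photoreceptor-layer thinning outside areas of
    retinal pigment epithelium (RPE) atrophy from en-face optical coherence
    tomography (OCT) thickness maps. Thickness maps of the outer nuclear
    layer (ONL), photoreceptor inner segments (IS) and outer segments (OS)
    are standardized to z-scores against an age-adjusted, location-specific
    normative model, features are extracted along evenly spaced
    distance-transform contour lines that travel with the growing atrophy
    boundary, and treatment-arm differences in change from baseline are
    estimated with linear mixed models, small-sample denominator degrees of
    freedom and single-step multiplicity adjustment. A synthetic-cohort
    generator emulates the longitudinal structure of a randomized geographic
    atrophy trial so the whole pipeline can be exercised and calibrated
    without access to trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    rlang,
    lme4,
    lmerTest,
    emmeans,
    EBImage,
    tiff,
    yaml,
    digest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pbkrtest,
    mvtnorm,
    jsonlite,
    ggplot2,
    withr
Config/testthat/edition: 3
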