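Package: cmskit
Title: Composite Measure Schemes for Comparative Severity Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and applies composite measure schemes (CMS) for
    comparative severity assessment of laboratory animals from
    multi-parameter behavioral and biochemical test batteries. Provides
    missingness and exclusion filtering of candidate parameters, Box-Cox
    normalization and z-scaling, resampling-based parameter selection by
    principal-component loading frequencies, construction of a
    directionality-aligned composite severity score, and per-animal
    severity-level assignment by repeated one-dimensional k-means
    clustering with bootstrap threshold confidence intervals. Includes a
    synthetic battery generator with planted group effects for validation
    and a reproducible end-to-end pipeline with frozen-scheme application
    to new animals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
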