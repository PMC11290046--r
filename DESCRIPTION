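Package: gp4pg
Title: Demographic Inference by Genetic Programming over Structured
    Population Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits demographic models to joint site-frequency-spectrum
    summaries of whole-genome polymorphism data by an invasive-weed
    evolutionary search over event graphs of structured populations
    (ecodemes containing stepping-stone topodemes), with soft population
    splits whose post-split migration decays exponentially toward an
    asymptote.  Includes a compiled structured-coalescent simulator with
    piecewise-constant epochs, the fourfold joint site frequency
    spectrum (4jSFS) summary statistic with block-bootstrap standard
    errors, a standardized-error fitness function, a VCF filtering and
    ancestral-polarization pipeline that produces the observed 4jSFS,
    and a principal-component goodness-of-fit diagnostic for fitted
    models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
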