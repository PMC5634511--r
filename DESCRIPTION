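Package: watershedd
Title: Upstream Watershed Condition and Childhood Diarrheal Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline linking upstream watershed condition to
    childhood diarrheal disease. Builds spatially routed water-source indices
    (the percent of accumulated water that fell as rain on human- or
    livestock-impacted land, and on tree-covered land) over a D8 drainage
    network; simulates DHS-style two-stage cluster surveys with binary
    diarrhea outcomes from a three-level random-intercept logit with known
    generating parameters; fits that model by maximum likelihood with nested
    Gauss-Hermite quadrature; and converts fitted coefficients into
    policy-comparable marginal effects at means with delta-method intervals,
    including tree-cover increase scenarios. All stages run on synthetic
    landscapes and surveys, so every result is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmmTMB,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
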