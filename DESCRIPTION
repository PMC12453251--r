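Package: oasim
Title: Reaction-Diffusion Simulation of Osteoarthritis Progression and Treatment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic simulator of osteoarthritis progression in an aging
    cohort (ages 50-90). A one-dimensional reaction-diffusion system tracks
    healthy, senescent and hypertrophic chondrocytes, calcified cartilage,
    MMP13 and collagen type II across the articular cartilage strip, with
    sex-specific postmenopausal terms. Includes drug-treatment dynamics for
    undenatured collagen type II (UC-II) injection and the senolytic fisetin,
    treatment-efficacy metrics, in-silico trial matrices over initiation and
    end ages, closed-form parameter calibration from published physiology,
    and LHS/PRCC global sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    lhs,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
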