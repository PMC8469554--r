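Package: pertflux
Title: Perturbation-Based Modeling of Autophagic Flux
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to infer the mode of action of perturbing agents on the
    autophagic flux from tandem mCherry-EGFP-LC3 sensor time courses. A
    three-reaction mass-action model (autophagosome formation, conversion to
    autophagolysosomes, lysosomal degradation) is simulated under binary-coded
    perturbation panels; candidate mode-of-action hypotheses for drugs with
    unknown autophagic activity are enumerated, fitted by weighted
    least-squares with particle swarm optimization, and ranked by objective
    value. Supporting stages implement two-channel puncta detection and
    AP/AL classification, Bliss-style cytotoxic interaction scoring, DAMP
    fold-change normalization, and a synthetic-data generator that emulates
    the kinetic imaging assay for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    EBImage,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    xml2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
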