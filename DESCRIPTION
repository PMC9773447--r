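Package: dsbfold
Title: Quantitative Modelling of Oxidative Protein Folding Capacity in
    Escherichia coli
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the demand that the Escherichia coli disulfide
    proteome places on the periplasmic Dsb enzyme system and the capacity
    that system provides. Ingests quantitative proteomes (copies per cell,
    ppm, molar concentration), merges disulfide-bond evidence from multiple
    sources and classifies bonds into folding-difficulty categories, builds
    a mass-action ordinary differential equation model of oxidative folding
    and isomerisation (DsbA/B and DsbC/G/D cycles), infers the minimal
    apparent rate constants compatible with proteome doubling under each
    growth condition, and predicts the spare capacity available for
    recombinant disulfide-bonded protein production. Includes a synthetic
    data generator so the full pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    xml2,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
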