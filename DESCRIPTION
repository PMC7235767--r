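Package: digestor
Title: Process Accounting and Lotka-Volterra Interaction Inference for
    Anaerobic Digester Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing chemically stressed anaerobic-digester
    microbiomes: stoichiometric process accounting (Buswell-Boyle
    theoretical methane potentials, organic loading rates, retention
    time, digestion efficiency, gas normalisation), 16S amplicon profile
    summarisation (read quality filtering, rank aggregation, Bray-Curtis
    dissimilarity and principal-coordinates ordination), cross-condition
    differential-shift classification with Benjamini-Hochberg control,
    and generalized Lotka-Volterra community simulation, gradient-matching
    interaction inference and sign-based ecological comparison.  Includes
    a synthetic study generator emulating a 4-reactor perturbation design
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    Biostrings,
    biomformat,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
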