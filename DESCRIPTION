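Package: ibdlogic
Title: Temporal Boolean Network Modelling of Inflammatory Bowel Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of qualitative logic models of immune
    signalling, centred on a 43-node Boolean network of the mucosal cytokine
    circuitry driving inflammatory bowel disease. Provides a small text
    language for Boolean rules extended with temporal window operators
    (a regulator must have been active in all, or any, of the previous N
    iterations), a fast discrete-time engine with synchronous and
    asynchronous updating, systematic single-node knockout screens with
    Perturbation Index classification and clustering, in-silico therapy
    simulation against the matrix-metalloproteinase tissue-damage readout,
    comparison of disease versus healthy steady states against literature
    annotations, and SBML-qual export for temporal-free models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    grid,
    xml2,
    ape,
    pheatmap
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
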