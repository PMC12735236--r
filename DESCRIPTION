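Package: isomalnet
Title: Neutral-Loss Annotation, Molecular Networking and Chemometrics for
    Isomalabaricane Chemotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for negative-mode LC-MS/MS dereplication of
    isomalabaricane triterpenoids in marine sponge extracts: exact
    monoisotopic mass and molecular-formula arithmetic for deprotonated
    ions, a declarative diagnostic neutral-loss rule engine that annotates
    MS/MS features with structural-class hypotheses, feature-based
    molecular networking by modified-cosine spectral similarity with
    mutual top-K edge pruning and family-size capping, and a
    sum-normalize/log/autoscale chemometrics stage with PCA and
    hierarchical clustering for chemotype discovery. A seeded synthetic
    corpus generator emulates the spectral grammar and two-chemotype
    abundance structure the analysis assumes, so the whole pipeline is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
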