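Package: pyrimqsar
Title: QSAR Modelling of Antiproliferative Pyrimidine and Uracil Derivatives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A 2D-descriptor QSAR workflow for modelling the antiproliferative
    activity (pIC50 against HeLa cells) of substituted pyrimidine and uracil
    derivatives. Parses SMILES into heavy-atom molecular graphs, computes
    centered and averaged Broto-Moreau topological autocorrelation descriptors
    (intrinsic-state, partial-charge, Sanderson-electronegativity and
    polarizability weightings) and molecular distance-edge descriptors between
    typed nitrogen atoms, ships a frozen published five-descriptor linear
    model, performs best multi-linear regression (BMLR) forward descriptor
    selection with collinearity control, intuitive-rational train/test
    splitting, internal and external validation statistics, and leverage-based
    applicability-domain analysis. Includes a deterministic synthetic-library
    generator for substituted pyrimidine scaffolds with planted linear
    activities for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
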