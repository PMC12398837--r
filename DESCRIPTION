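Package: whalescreen
Title: Ligand-Based Virtual Screening with WHALES 3D Molecular Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scaffold-hopping virtual screening of small-molecule libraries
    with WHALES (Weighted Holistic Atom Localization and Entity Shape)
    descriptors. Molecules are embedded in 3D, minimized under the MMFF94
    force field and assigned Gasteiger-Marsili partial charges via OpenBabel;
    per-atom isolation, remoteness and isolation/remoteness-ratio indices are
    derived from atom-centered Mahalanobis distance matrices and summarized
    into a 33-value descriptor per molecule. The package ranks a library
    against multiple query templates by Euclidean descriptor distance,
    applies drug-likeness property window filters (molecular weight, logP,
    hydrogen-bond donors/acceptors, topological polar surface area), combines
    MM/GBSA end-point binding energy components, and generates seeded
    synthetic screening libraries with planted structural analogs for
    retrieval benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    ChemmineOB,
    optparse,
    jsonlite,
    withr
SystemRequirements: OpenBabel (>= 3.0, 'obabel' on the PATH); Python (>= 3.9) with
    RDKit, for 3D preparation
Config/testthat/edition: 3
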