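Package: hgetaway
Title: Interpretable H-GETAWAY (HATS) Molecular Descriptors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computes leverage-weighted autocorrelation (HATS) molecular
    descriptors of the H-GETAWAY family from explicit-hydrogen 3D structures,
    keeping the full atomic-pair bookkeeping so that a descriptor value can be
    traced back to individual atom pairs, substituents and molecular geometry.
    Provides the molecular influence matrix and atomic leverages, topological
    (graph-distance) lag selection, carbon-scaled atomic weighting schemes,
    intra-/inter-fragment decomposition of descriptor values, substructure
    cutting, and conformer shape clustering on pair-contribution fingerprints
    (UPGMA with cophenetic validation). Includes programmatic generators for
    reference structures (fullerene C60, n-alkanes, hexabenzocoronene,
    halobenzenes, synthetic conformer sets).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    igraph,
    jsonlite,
    ChemmineR,
    bio3d,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
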