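Package: hemescan
Title: Heme Porphyrin Distortion Analysis, Local Outlier Factors and
    Reaction Energy Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the out-of-plane distortion of heme porphyrin
    macrocycles and the energetics of heme-catalysed reactions. Extracts and
    canonically orders the 24-atom porphyrin macrocycle from PDB or mmCIF
    structures, decomposes its out-of-plane displacement into symmetry-adapted
    normal-coordinate modes (ruffling, doming, saddling, waving, propellering),
    scores distortion features with an exact Local Outlier Factor implementation
    including k-sweeps, reference curves and percentile ranks, and represents
    reaction pathways as graphs of stationary points with per-step barriers,
    route bottlenecks, reaction energies and Eyring rate-barrier conversion. A
    curated stationary-point energy fixture for the N2O-forming step of
    fungal nitric oxide reductase (P450nor) and seeded synthetic-data
    generators are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
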