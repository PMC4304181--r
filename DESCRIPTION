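Package: sectorscan
Title: Protein Sector Identification by Statistical Coupling Analysis
Version: 0.1.0
Authors@R:
    person("Sector", "Scan Developers", email = "sectorscan@example.org",
           role = c("aut", "cre"))
Description: Identifies protein sectors (groups of co-evolving residues) from
    a multiple sequence alignment using statistical coupling analysis:
    positional conservation by relative entropy, a conservation-weighted
    positional covariance matrix, eigenvalue significance against
    within-column shuffled null alignments, and independent component
    analysis to sharpen sector boundaries. Maps sectors onto PDB structures,
    annotates disease-associated substitutions by sector and sequence
    region, and exports structure-coloring artifacts (B-factor encoded PDB,
    Jmol and PyMOL scripts). Includes alignment curation operators
    (redundancy clustering, gap filtering, reference trimming) and a
    synthetic-data module that plants co-evolving sectors for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
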