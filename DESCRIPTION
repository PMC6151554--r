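Package: critres
Title: Classification of Critical Residues for Protein Function from
    Structure-Derived Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify residues critical for protein function from
    protein structure. Builds residue contact graphs from PDB files, computes
    eleven contact-graph centrality descriptors and a structure-based
    correlated-mutation index from multiple sequence alignments, scores
    residue criticality from site-directed mutagenesis tables via a
    rank-based criticality index over physicochemical substitution distances,
    filters descriptor tables (constant, Spearman-redundancy and
    information-gain filters), selects descriptor subsets with a genetic
    algorithm wrapped around a class-weighted linear support vector machine
    scored by cross-validated Matthews correlation, and evaluates models with
    leave-one-out, swapped-set and model-overlap harnesses. Synthetic
    generators for structures, alignments, mutagenesis tables and feature
    tables make the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Biostrings,
    foreign,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
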