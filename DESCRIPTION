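Package: foldcensus
Title: Fold-Dependent Census of Protein Conformational Heterogeneity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Compares multi-conformer experimental ensembles of protein
    domains against a single predicted reference structure and scores each
    fold for rigidity versus conformational heterogeneity. Provides PDB and
    mmCIF ingestion with CATH-style domain extraction, glocal sequence
    alignment with one-on-one residue mapping onto full-length predicted
    models, Kabsch superposition with length-normalized RMSD100, geometric
    compactness metrics (solvent-accessible surface area, molecular volume,
    buried-to-exposed residue ratio), secondary-structure assignment,
    two-level sequence-identity and topology sub-clustering, per-fold census
    aggregation with robust dispersion statistics, region-wise
    conformational clustering, and hypergeometric enrichment between
    heterogeneous-fold and consistent-fold protein sets. Ships a seeded
    synthetic-ensemble generator with controlled hinge amplitude so the
    full pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    cluster,
    jsonlite,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
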