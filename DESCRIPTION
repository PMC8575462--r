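Package: phosphoSLiM
Title: Scanning and Structural Modeling of the PP2A/B55alpha Substrate SLiM
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the phosphatase-substrate short linear motif (SLiM)
    p[ST]-P-x(4,10)-[RK]-V-x-x-[VI]-R recognised by the PP2A/B55alpha
    holoenzyme. Provides a PROSITE-style pattern grammar with variable gaps,
    proteome-wide scanning with phospho-to-anchor spacing statistics, exact
    hypergeometric enrichment tests over interactor sets, mining of peptide
    fragments from macromolecular coordinate files, backbone-dihedral
    clustering (DBSCAN on a max-circular-torsion metric), rigid-body
    superposition, and anchor-constrained placement of a phosphopeptide
    spanning a phosphatase active site and a regulatory-subunit anchor
    residue. Ships deterministic synthetic-data generators (planted-motif
    proteomes, conformer libraries, mock anchor scenes) with ground-truth
    records for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
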