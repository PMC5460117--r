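Package: PSNet
Title: Contact-Based Protein Structure Networks from Structural Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted Protein Structure Networks (PSNs) from
    multi-frame structural ensembles using distances between side-chain
    centers of mass. Edges are weighted by contact persistence (the
    fraction of frames in which a residue pair is within a distance
    cutoff) and filtered at a critical persistence threshold. The package
    computes the two fundamental PSN properties, hub residues and
    connected components, attaches Jackknife-resampling standard errors
    to them, and scans a grid of distance cutoffs to characterize the
    fragmentation-to-percolation behaviour of the network. A synthetic
    ensemble generator with exactly known contact persistence supports
    testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    tools,
    utils,
    bio3d,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'PSNet-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'ensemble-io.R'
    'mass-table.R'
    'sidechains.R'
    'psn-construction.R'
    'graph-analysis.R'
    'jackknife.R'
    'cutoff-scan.R'
    'report.R'
    'synthetic.R'
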