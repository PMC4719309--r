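Package: chirpevo
Title: Comparative Discovery of lncRNA Orthologs and Evolution of Their
    Genomic Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for locating long noncoding RNA (lncRNA) orthologs across
    related genomes by combining synteny anchors, short sequence motifs
    ("microhomology") scored with exact position-weight-matrix p-values, and
    hairpin secondary-structure scoring, with iterative refinement of the
    motif along a phylogeny.  Companion analyses for ChIRP-seq occupancy maps
    of such lncRNAs: windowed signal enrichment, Muller-element scaffold
    assignment from chain scores, peak filtering, cross-species peak
    conservation and turnover against permutation nulls, polypyrimidine-tract
    selection with a distance penalty and peak-to-tract proximity statistics,
    motif orientation-bias tests, and nearest-neighbor spacing analyses.  A
    synthetic multi-species data generator with planted ground truth makes
    the whole pipeline testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    ape,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
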