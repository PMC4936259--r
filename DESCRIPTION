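Package: corebild
Type: Package
Title: Bayesian Core-Block Detection and Homologous-Region Delineation in
    Protein Multiple Alignments
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects conserved "core blocks" in protein multiple sequence
    alignments using Bayesian Integral Log-odds (BILD) column scores under
    Dirichlet-mixture priors, clusters sequences into subfamilies, links
    blocks across subfamilies with a Bayesian column-pair relatedness score,
    flags inconsistent (badly predicted) sequence segments by a
    posterior-predictive criterion, chains blocks into homologous regions
    relative to a user-designated query sequence, and removes and ranks
    sequences by their homology to the query. Includes a deterministic
    synthetic-alignment generator with planted ground truth for validation.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
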