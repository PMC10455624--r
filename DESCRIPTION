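Package: barcodegap
Title: DNA Barcode Gap Analysis for Aligned Barcode Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the DNA barcode gap - the separation between
    intra-specific and inter-specific pairwise genetic distances - from
    aligned barcode matrices such as the fungal nrITS region and its ITS1
    and ITS2 sub-regions. Computes raw (p-distance) and Kimura two-parameter
    pairwise distances with pairwise deletion, patristic distances from
    phylogenetic trees, pools distances within and between species under
    alternative species partitions (lumping/splitting), and performs a
    quantile-based barcode-gap stress test with summary report tables.
    Includes a seeded synthetic alignment generator with controlled
    divergences, transition/transversion bias and region rate structure so
    the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: ape, seqinr, stats, utils, graphics, optparse, yaml
Suggests: testthat (>= 3.0.0), igraph, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
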