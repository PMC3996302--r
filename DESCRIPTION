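Package: blsom
Title: Batch-Learning Self-Organizing Maps for Alignment-Free Genome Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters genomic sequence fragments by their oligonucleotide
    composition ("genome signature") with a batch-learning self-organizing
    map (BLSOM). Provides strand-degenerate (reverse-complement summed)
    k-mer counting, PCA-based lattice initialization, order-independent
    batch training, assignment of new fragments to a trained map, and
    diagnostic lattice layers: U-matrix, category coloring, G+C% quantile
    bins, observed/expected oligonucleotide ratios and detection of
    compositionally peculiar map zones. Includes a Markov-chain genome
    simulator so the whole workflow is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    grDevices,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
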