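Package: spliceRNN
Title: Splice-Site Identification and Exon Prediction with a Bidirectional
    LSTM Sequence Classifier
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies splice-site donor (GT) and acceptor (AG) dinucleotides in
    eukaryotic genomic DNA and assembles exon/intron gene structures from the
    calls. From genomic FASTA input the package extracts open reading frames,
    builds a three-class (donor / acceptor / no-site) training set of 60-nt
    windows with an ordinal nucleotide encoding, trains a four-layer
    bidirectional long short-term memory (LSTM) recurrent classifier
    (embedding, dropout, bidirectional LSTM, dense softmax; implemented in
    C++ via Rcpp), and calls introns on new sequence under a configurable
    intron length constraint (default 70-100 nt). A seeded synthetic-genome
    simulator with ground-truth annotation makes every stage testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    graphics,
    tools,
    methods
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
NeedsCompilation: yes
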