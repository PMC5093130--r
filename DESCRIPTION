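Package: heveinscan
Title: Discovery and Classification of Hevein-Like Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for the in-silico discovery and classification of
    hevein-like chitin-binding peptides, with emphasis on the Pro-rich
    8-cysteine class typified by the ginkgotides of Ginkgo biloba.
    Provides cysteine-framework detection and intercysteine loop
    decomposition, chitin-binding-domain motif scanning, peptide mass
    arithmetic under disulfide and S-alkylation states, isoelectric point
    prediction, precursor three-domain parsing with a Gly|Asp cleavage
    rule, a five-criterion homolog filter with cross-plant mature-domain
    deduplication, enumeration and ranking of disulfide connectivity
    patterns, neighbor-joining phylogenetics with Newick output,
    sequence-logo profile matrices, six-frame translation and ORF
    finding, and a seeded synthetic-data generator that reproduces the
    composition of the transcriptome homolog screen for end-to-end
    testing without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
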