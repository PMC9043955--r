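Package: ribomine5s
Title: Mining 5S rDNA Ribotypes and Intergenic-Spacer Features from Short Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for reconstructing 5S ribosomal DNA repeat units from short
    sequencing reads and characterizing the intergenic spacer (IGS) within a
    genome. The pipeline filters reads with coding-sequence probes, assembles a
    k-mer graph of the tandem array, extracts complete repeat units (one full
    IGS flanked by coding-sequence fragments), deduplicates them into ribotypes
    with a pseudogene-exclusion rule, estimates each ribotype's relative genomic
    content by read map-back, and classifies ribotypes as major, minor or rare.
    Companion tools compute IGS descriptive features (GC content, lengths,
    pairwise similarity with long-indel masking), detect internal tandem
    duplications, scan RNA polymerase III promoter and terminator motifs, type
    structural variants from indel signatures, and build median-joining
    haplotype networks. A seeded simulator generates tandem arrays with known
    ribotype structure so the whole pipeline is testable without downloads.
License: GPL (>= 3)
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    igraph,
    jsonlite,
    Matrix,
    pracma,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
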