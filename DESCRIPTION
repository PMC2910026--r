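Package: tagtrimr
Title: Detection, Trimming and Filtering of Amplification Tag Sequences in
    Sequencing Reads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies and removes artificial tag sequences (primers,
    adaptors, MID barcodes) from FASTA/FASTQ reads produced by primer-based
    amplification protocols such as Whole Transcriptome Amplification.
    Tags are located by an IUPAC-aware bit-parallel semi-global matcher
    that tolerates insertions, deletions and substitutions; unknown tags
    are predicted automatically from per-position nucleotide frequencies
    at the read ends with k-mer based shift correction.  Reads carrying
    internal tag-to-tag junctions from blunt-end fragment concatenation
    are split into their constituent fragments, and trimmed reads are
    filtered by length, ambiguous-base content, tag occurrence and exact
    duplication.  A ground-truthed synthetic read generator supports
    end-to-end validation without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    S4Vectors,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
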