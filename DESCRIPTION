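Package: polyqscan
Title: Codon Architecture of Polyglutamine Stretches in Coding Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects maximal runs of glutamine codons (CAA/CAG) in protein-coding
    transcripts and quantifies their codon architecture: background and
    length-specific CAG/CAA usage, within-stretch codon positioning, nucleotide
    similarity (Hamming distance) between stretches and their flanking codons,
    amino-acid context of the flanking positions, an exact null model for the
    longest identical-codon run under independent codon choice, and four-codon
    pattern decomposition. Includes a synthetic-transcriptome generator with
    known ground truth so every stage of the analysis can be validated without
    external data, and a pipeline driver that runs all stages across multiple
    species datasets reproducibly.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
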