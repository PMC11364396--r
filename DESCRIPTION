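Package: hyperedit
Title: Genome-Wide A-to-I RNA Editing Detection with Hyper-Editing Rescue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for genome-wide adenosine-to-inosine (A-to-I)
    RNA editing analysis from stranded paired-end RNA-seq. Includes a
    synthetic-data generator with planted editing ground truth, an ungapped
    read aligner with hyper-edited read rescue via an A-to-G transformed
    pseudo-genome, strand-aware per-site pileup and edit-ratio calling with
    cohort-level high-confidence filters, per-site differential editing
    (Fisher's exact test with Benjamini-Hochberg FDR), genomic region and
    repeat-class annotation, codon consequence calls, splice-site proximity
    checks, positional motif enrichment, downstream A-rich satellite
    detection, and inverted-repeat (dsRNA stem-loop) scanning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    data.table,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
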