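Package: asrnadesign
Title: Genome-Wide Design of Bacterial Antisense RNAs with Off-Target
    Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Designs antisense RNAs (asRNAs) for every annotated coding
    sequence in a bacterial genome, for use in systematic knockdown
    libraries. Each asRNA is the perfect reverse complement of a
    fixed-length window positioned relative to the start codon (defaults:
    21 nt at offset -8, overlapping the Shine-Dalgarno region). Every
    candidate is screened genome-wide for off-target binding sites with a
    built-in seed-and-extend ungapped matcher (an external BLAST+ backend
    is optional); flagged genes are redesigned exactly once at a
    downstream offset and re-screened. Reads GenBank and EMBL annotation,
    writes CSV reports with full screening evidence, and includes a
    deterministic synthetic-genome generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    optparse,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
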