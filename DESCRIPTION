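Package: splicepanel
Title: Splice-Variant Interpretation from Targeted Blood RNA Panel Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies splice junctions from gapped read alignments against a
    transcript model, detects and types aberrant splicing events (exon
    skipping, cryptic splice-site use, intron retention and tandem-duplication
    back-junctions), converts junction fractions into allele-level effect
    estimates with nonsense-mediated-decay exclusion logic, triages variants by
    SpIP- and SpliceAI-style splice predictions, and combines RNA and clinical
    evidence into ACMG-AMP 1-5 classifications with strength modifiers. A
    spliced-read simulator with known ground truth emulates the scenarios seen
    on a 48-gene hereditary-cancer RNA panel, and the panel's 53-variant
    evidence table is packaged as a plain-text fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    stats,
    tibble,
    tools,
    utils
Suggests:
    BiocGenerics,
    GenomicAlignments,
    Rsamtools,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
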