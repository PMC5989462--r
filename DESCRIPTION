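Package: syntenic
Title: Synteny Block Construction, Analysis and Visualization from
    Whole-Genome Alignment Anchors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds synteny blocks (conserved genomic segments between a
    reference genome and one or more target genomes) from pairwise
    whole-genome alignment anchors such as the ungapped blocks of UCSC
    chain files, at a user-chosen resolution.  Unifies third-party synteny
    block definitions (Satsuma, Cinteny, SyntenyTracker and generic
    tables) into one plain-text format, classifies inter- and
    intra-chromosomal rearrangements, relates gene annotations to block
    boundaries (conserved, lineage-specific and rearrangement-broken
    genes), and renders Circos-style circular and linear synteny plots as
    deterministic SVG plus a static HTML site.  Ships a rearrangement
    simulator that plants inversions, translocations, fissions, fusions
    and transpositions with an exact ground-truth block decomposition, so
    the whole pipeline is testable without external genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
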