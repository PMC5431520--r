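Package: mitorfan
Title: Comparative Mitogenomics of Doubly Uniparental Inheritance in Bivalves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated circular
    mitochondrial genomes, built around the features that distinguish
    female- and male-transmitted (F and M) mtDNA lineages of freshwater
    mussels and other bivalves with doubly uniparental inheritance (DUI).
    Provides GenBank flat-file input/output for annotated mitogenomes,
    extraction and sequential numbering of unassigned regions, an open
    reading frame census under the invertebrate mitochondrial genetic code
    with dual start-codon translation policies, a homology-screen ladder
    based on local alignment, Nei-Gojobori dN/dS and p-distance statistics
    with Jukes-Cantor correction, relative synonymous codon usage and base
    composition summaries, k-of-n consensus combination of alignment site
    masks, signed circular gene-order comparison with breakpoint distance
    and single-step tandem duplication-random loss (TDRL) feasibility
    testing, pseudogene-fragment and tandem-repeat scanners,
    neighbor-joining trees with gender-joining versus taxon-joining
    transmission-pattern classification, and a fully deterministic
    synthetic mitogenome simulator with known ground truth for end-to-end
    validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    jsonlite,
    optparse
Config/testthat/edition: 3
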