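Package: mito12s
Title: Mitochondrial 12S rRNA Deafness-Variant Screening Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Case-control screening pipeline for mitochondrial 12S rRNA
    (MT-RNR1) variants associated with aminoglycoside ototoxicity and
    nonsyndromic hearing loss. Calls homoplasmic variants from Sanger-style
    amplicon sequences against an rCRS-coordinate reference, computes a
    14-primate conservation index per position, annotates variants on a
    curated rRNA secondary-structure model (stem/loop location and
    Watson-Crick pairing effects), applies a three-criterion pathogenicity
    classifier with known-mutation and haplogroup-marker registries,
    computes cohort allele frequencies, pure-tone averages and five-grade
    hearing-loss severity, and co-screens the GJB2 coding region. Includes
    a synthetic-data module that generates primate alignments with
    controlled per-position conservation and cohorts with planted variants,
    so every stage is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
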