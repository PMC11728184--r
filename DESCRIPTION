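Package: mobilomekit
Title: Mobilome-Seq eccDNA Detection, LTR Dating and Insertion Landscape
    Analysis for Active LTR Retrotransposons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pipeline components for characterising transpositionally
    active LTR retrotransposons from Mobilome-Seq style data: per-element
    eccDNA enrichment testing between Plasmid-Safe treated (PS+) and
    untreated (PS-) libraries with a two-sided Fisher exact test and a
    coverage-breadth curation filter; insertion-time estimation from LTR
    pair divergence under the Kimura two-parameter model (T = K/2r);
    family clustering and assignment of LTR sequences under the 80-80-80
    rule with majority-rule consensus extraction; centromere and
    pericentromere annotation from repeat-hit density with compartment and
    genic classification of transposon insertion polymorphisms (TIPs);
    six-frame ORF discovery with nested-ORF removal and conservation
    surveys of additional ORFs across element families.  A seeded
    synthetic-data generator emulates every input with known ground truth
    so the whole pipeline is testable at desk scale.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    methods
Suggests:
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
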