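Package: psijunc
Title: Junction-Read Quantification and Differential Alternative Splicing
    from Two-Condition RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Junction-read based analysis of alternative splicing between two
    conditions (e.g. control versus factor knockdown). Derives a splice
    junction catalog from GTF/GFF3 annotation, extracts junction counts from
    spliced SAM alignments or STAR SJ.out.tab tables, discovers cassette-exon
    and alternative 5'/3' splice-site events, quantifies percent spliced in
    (PSI) per condition, tests differences with an exact test and
    Benjamini-Hochberg FDR control, and classifies calls into six directional
    categories. Companion tools annotate non-productive isoforms for
    nonsense-mediated decay (NMD) sensitivity under the 50-nt rule, score
    5' splice-site (donor) 9-mers with table-backed or PWM models, engineer
    minigene constructs with exact coordinate maps and donor-site mutations,
    and simulate seeded two-condition experiments with known truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
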