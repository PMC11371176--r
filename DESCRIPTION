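Package: paskit
Title: Antisense Transcription, mRNA Decay Kinetics and Freezing-Tolerance
    Analysis for the Plant Cold Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for analysing antisense (PAS-gene) transcription in the
    Arabidopsis cold response from strand-specific nascent-transcription
    coverage. Classifies host genes by the geometric antisense-initiation
    rule (3'-half of the gene or 20% of gene length downstream), performs
    negative-binomial Wald differential expression with median-of-ratios
    normalisation and Benjamini-Hochberg correction, compares nascent and
    steady-state responses, estimates mRNA half-lives from transcription
    inhibition time courses (t1/2 = ln2/slope), computes strand-aware
    metagene profiles around the +1 nucleosome and over scaled gene bodies,
    and fits four-parameter logistic electrolyte-leakage curves with LT50
    estimation and extra sum-of-squares F-tests between genotypes. A
    synthetic-data module generates all inputs from an explicit
    transcription-decay kinetic model so every stage is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    yaml,
    jsonlite,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
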