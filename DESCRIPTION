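Package: chloredit
Title: Quantification of Chloroplast C-to-U RNA Editing from Small RNA
    Libraries and Allele-Specific qPCR
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify cytidine-to-uridine RNA editing in plastid
    transcripts. Implements a three-round subtractive short-read alignment
    (chloroplast exact match, nuclear/mitochondrial subtraction, relaxed
    chloroplast match), pileup-based per-site editing-fraction estimation
    with a binomial detection test and between-condition t-tests, plastid
    gene-expression counting with median-of-ratios normalization, and
    allele-specific RT-qPCR editing-efficiency estimation (Ct calling,
    window-of-linearity amplification-efficiency estimation, efficiency
    filtering and Ct-ratio based edited-fraction computation). A fully
    seeded synthetic-data generator emulates the study design end to end:
    reference genomes, editing-site tables, small RNA libraries with
    planted per-condition editing fractions, and 384-well qPCR plates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    grDevices,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
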