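Package: cagptools
Title: Differential Expression, Gene-Program Construction, and NanoString
    Normalization for Early Gonadal Transcriptomics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reimplements, as a tested analysis workflow, the computational
    chain behind a developmental-transcriptomics study of insulin/IGF
    signaling in mouse gonadal somatic progenitors: moderated t-statistic
    differential expression with intensity, fold-change and FDR filters;
    construction of a core adreno-gonadal program (genes up-regulated in
    both sexes before sex determination) and its overlap with dimorphic,
    primed and mutant-affected gene sets; and a complete NanoString
    nCounter count-processing chain (negative-control background
    correction, positive-control QC, geNorm reference-gene selection,
    geometric-mean normalization) with per-gene sources-of-variation
    ANOVA. A synthetic-data module generates expression matrices and
    count tables with planted ground truth so every stage is testable
    without the original array data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    limma,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
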