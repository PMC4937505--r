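Package: casptrace
Title: Multi-Omics Kinetic Profiling of Caspase Substrates During ER Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for integrating caspase substrate profiling (neo-C-terminal
    aspartate peptides quantified with TMT6plex isobaric labels), global
    protein profiling, and RNA-seq time courses to characterise the dual
    post-translational and transcriptional regulatory roles of caspases
    during endoplasmic reticulum stress. Provides TMT reporter-ion
    extraction, target-decoy false discovery rate control with linear
    discriminant scoring, cleavage-site mapping and motif matrices, fuzzy
    c-means trajectory clustering, three-layer trajectory overlay with
    correlation-based regulatory-mode classification, voom/limma
    differential expression, competitive gene-set testing with inter-gene
    correlation adjustment, transcription-factor dual-regulation calling,
    and a synthetic-data generator with planted ground truth so the whole
    pipeline is exercisable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    fgsea,
    generics,
    ggplot2,
    jsonlite,
    limma,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    ape,
    DESeq2,
    e1071,
    MASS,
    mclust,
    optparse,
    readr,
    SummarizedExperiment,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
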