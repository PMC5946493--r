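Package: gbepi
Title: Gene-Body Epigenomic Integration of Methylation, Hydroxymethylation,
    ChIP Signal and Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-centric integration of DNA methylation from HELP-tagging
    angle tables, 5hmC pulldown coverage, ChIP signal and expression
    microarray data. Derives strand-aware promoter (TSS +/- 2 kb) and
    gene-body (TSS + 2 kb to TES) regions from gene models, merges
    per-sample HpaII methylation angles into an analysed-site universe,
    summarizes angles and fragment FPKM per region, clusters expression
    profiles into twelve groups and labels them cell-type-specific or
    constitutive, calls gene-body accumulated genes from length-normalized
    ChIP signal, builds gene-body-centred metaplots, compares gene-length
    distributions between clusters by Kolmogorov-Smirnov testing, and
    computes qPCR-based percent 5hmC and hMeDIP enrichment. Includes a
    deterministic synthetic multi-omics data generator with planted group
    structure so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Rsamtools,
    rtracklayer,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
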