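Package: HoLAMap
Title: Causal-Variant Pinpointing by Observed-Heterozygosity Scans Across
    Biparental Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fine-maps causal variants underlying QTL that co-localize in
    multiple biparental crosses. Scans the observed-heterozygosity (Ho)
    index -- the fraction of QTL-detecting crosses whose founder and
    reference parents carry different alleles at a SNP -- across a candidate
    region, intersects it with candidate-region association mapping under a
    naive linear model or a structure-corrected GLM, and annotates candidate
    clusters against gene models. Includes tail-selection and cross-number
    Monte-Carlo power estimators for experimental design, windowed
    nucleotide diversity with per-site missing-data correction, and a
    synthetic-data generator emulating a structured inbred diversity panel
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    vcfR,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
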