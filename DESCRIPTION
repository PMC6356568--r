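Package: sireDMR
Title: Father-Sorted Differential Methylation Analysis for RRBS Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and validation of differentially methylated regions
    (DMRs) between father-sorted groups of offspring from reduced
    representation bisulfite sequencing (RRBS) count tables. Implements
    per-CpG Fisher exact testing on pooled counts with Benjamini-Hochberg
    correction and gap-based region merging, a site-wise shuffle
    (permutation) estimate of the chance DMR count, promoter/CDS/CpG-island
    annotation of DMRs, k-of-n replication filtering across sires,
    cross-environmental-factor gene-set comparison, and an offline
    interaction-network edge-count enrichment test. Includes a synthetic
    RRBS data generator with a pedigree/treatment structure and planted
    regional methylation shifts so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    GenomicRanges,
    IRanges,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
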