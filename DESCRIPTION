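Package: gwasfly
Title: Cross-Species Nomination and Conservation Profiling of GWAS Candidate Genes in Drosophila
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nominates human candidate susceptibility genes from GWAS
    association signals under four nested genomic criteria (intragenic,
    nearest neighbors, within 250 kb, within 500 kb), calls their
    conservation in Drosophila by integrating per-algorithm ortholog
    predictions into DIOPT-style vote scores (conserved at score >= 2),
    and summarizes conservation, tissue expression (RPKM >= 2), phenotype,
    and essentiality enrichment by trait category. Ships a synthetic-data
    generator that emulates the GWAS catalog, gene annotation, ortholog
    prediction, tissue RPKM, and phenotype-term resources with known
    ground truth, so the whole pipeline can be exercised and validated
    end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
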