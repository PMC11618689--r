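Package: raretrio
Title: Rare-Variant Segregation and Prioritization in Family Exome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for rare-variant analysis in familial
    autism spectrum disorder exome cohorts. Reads multi-sample VCFs, pedigrees,
    variant annotation and gene-constraint tables; applies per-genotype quality
    filters and rare/novel/private frequency classification; calls de novo,
    compound heterozygous, inherited homozygous, and X-linked variants with
    pedigree-aware segregation rules; prioritizes candidates through a
    seven-step ladder (cross-family dedup, SFARI/OMIM gene tiering, recurrence,
    deleteriousness and constraint ranking, ClinVar and gnomAD homozygote
    filters) plus a gene-length-normalized missense-rate filter for oversized
    genes; post-processes CNV segments (outlier samples, significance and log2
    thresholds, cross-family dedup, known-locus overlap, structural-variant
    frequency containment); and computes cohort statistics (burden comparison,
    phenotype prevalence, demographics, parental-age analyses, Fisher/BH
    specific-expression enrichment). Includes a synthetic cohort generator that
    plants labeled truth for every inheritance class and filter decoy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
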