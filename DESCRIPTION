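Package: heritkit
Title: SNP and Twin Heritability of Polygenic Traits with Annotation
    Partitioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the proportion of phenotypic variance captured by
    common SNPs with genetic-relationship-matrix (GRM) mixed linear models
    fitted by average-information restricted maximum likelihood, partitions
    that variance across genomic annotation categories (genic/intergenic and
    evolutionary-conservation classes smoothed by linkage-disequilibrium
    weighting), and estimates classical twin-design ACE heritability for
    comparison. Includes PLINK bed/bim/fam and GCTA GRM binary I/O,
    genotype quality control, relatedness pruning, GRM principal components,
    regional-phenotype preparation, and a synthetic-data generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    Matrix,
    methods,
    purrr,
    rlang,
    rtracklayer,
    splines,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
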