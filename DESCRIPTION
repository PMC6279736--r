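Package: mqtlkit
Title: Methylation QTL Mapping and Partitioning of Complex-Trait Heritability
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A two-cohort pipeline for the discovery and replication of cis and
    trans methylation quantitative trait loci (mQTL) from SNP dosages and
    Illumina-style beta-value methylation matrices, together with the
    downstream analyses such mappings feed: probe-SNP overlap accounting,
    ANNOVAR-style positional annotation with category precedence, subtelomeric
    and per-chromosome distribution tests, stratified LD score regression that
    partitions GWAS heritability into an mQTL component and the rest of the
    genome, and MAF- and annotation-matched SNP resampling nulls for
    enrichment testing. A synthetic-data module generates two-cohort genotype
    panels with local LD, beta-distributed methylation with planted cis/trans
    effects and covariate structure, toy gene models, and GWAS chi-square
    summary statistics, so that every stage of the pipeline is testable
    without access to cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    data.table,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Epigenetics, MethylationArray, SNP, GenomeWideAssociation,
    FunctionalGenomics, Software
RoxygenNote: 7.3.3
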