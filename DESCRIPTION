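Package: polyqprofiler
Title: Genomic Characterization and Drug-Target Risk Profiling of Polyglutamine Disorder Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for the unbiased genomic characterization
    of polyglutamine (polyQ) disorder genes from snapshot tables of GWAS
    gene-trait catalogs. Provides phenome-wide filtering of gene-trait
    associations by locus-to-gene (L2G) score with threshold-robustness
    sweeps, trait prioritization (count-trait removal, peer-review provenance
    filtering, per-gene trait deduplication, ancestry summaries, OMIM-style
    phenotype classification), identification of independent association
    signals (haplotypes) by linkage-disequilibrium pruning of index variants
    with tag-variant selection, weighted gene-gene networks of shared trait
    associations, and drug-target genomic safety scoring (constraint, tissue
    specificity, molecular interactions) with tie-corrected rank-sum
    comparison of gene sets. Includes seeded synthetic-data generators and
    packaged fixtures so every stage is exercisable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
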