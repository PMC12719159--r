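#' @title Packaged in-study fixtures
#' @description
#' Builders for the packaged fixture tables used throughout the tests and
#' vignette: the 38-row catalog of high-confidence GWAS associations linked
#' to five polyQ disorder genes with their per-variant annotations and
#' haplotype structure; the 215-record provenance catalog; the 10-gene
#' druggability feature profiles; the OMIM-style phenotype entries; and a
#' 41-study ancestry table. Trait labels, L2G/CADD scores, p-values,
#' effects, allele frequencies and haplotype groupings are transcribed
#' study values; genomic positions, study identifiers and PubMed ids are
#' synthetic placeholders (the originals are not part of the snapshot), and
#' the LD matrices are synthetic block matrices consistent with the
#' haplotype grouping. The same tables are shipped as TSV files under
#' `inst/extdata/` and regenerate bit-identically from these builders.
#' @name polyq-fixtures
NULL

POLYQ_GENES <- c("AR", "ATN1", "ATXN1", "ATXN2", "ATXN3", "ATXN7",
                 "CACNA1A", "HTT", "TBP", "THAP11")

table1_gene_meta <- function() {
  tibble(
    gene_symbol = c("ATXN1", "ATXN2", "ATXN7", "CACNA1A", "HTT"),
    gene_id = c("ENSG00000124788", "ENSG00000204842", "ENSG00000163635",
                "ENSG00000141837", "ENSG00000197386"),
    chrom = c("6", "12", "3", "19", "4"),
    base_pos = c(16300000L, 111450000L, 63860000L, 13200000L, 3040000L)
  )
}

# haplotype structure: per gene, ordered blocks; tag listed first in each
table1_haplotype_members <- function() {
  list(
    ATXN1 = list(
      "rs719316",
      "rs17603856",
      c("rs909788", "rs6459480", "rs9297016", "rs7772172"),
      "rs6459472",
      c("rs9367926", "rs6915310"),
      "rs2237199",
      c("rs7770062", "rs73366713"),
      "rs3819405"
    ),
    ATXN2 = list("rs653178", "rs848130"),
    ATXN7 = list("rs832190", "rs3821902", "rs13434089"),
    CACNA1A = list("rs5021328", "rs16003"),
    HTT = list(
      "rs363096",
      c("rs61348208", "rs7685686", "rs82334", "rs2071703"),
      "rs113928896",
      "rs362307",
      "rs6828882",
      "rs2798297"
    )
  )
}

table1_variant_positions <- function() {
  meta <- table1_gene_meta()
  members <- table1_haplotype_members()
  rows <- purrr::map(meta$gene_symbol, function(g) {
    haps <- members[[g]]
    base <- meta$base_pos[meta$gene_symbol == g]
    purrr::map2(haps, seq_along(haps), function(vs, h) {
      tibble(gene_symbol = g, variant_id = vs,
             pos = base + h * 10000L + (seq_along(vs) - 1L) * 100L,
             haplotype_index = h,
             tag = vs[1])
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}

table1_rows <- function() {
  # gene | trait | study | variant | p | effect | ci_lo | ci_hi | type | l2g | category
  or <- "odds_ratio"; be <- "beta"
  rows <- list(
    list("ATXN1", "multiple sclerosis", "IMSGC_2011", "rs719316", 2.00e-13, 1.07, 1.05, 1.09, or, 0.79, "disease"),
    list("ATXN1", "systemic lupus erythematosus", "Morris_2016", "rs17603856", 3.00e-12, 0.88, 0.85, 0.91, or, 0.79, "disease"),
    list("ATXN1", "cognitive ability, years of educational attainment or schizophrenia", "Lam_2017", "rs6459480", 2.00e-10, NA, NA, NA, NA, 0.69, "measurement"),
    list("ATXN1", "household income", "Hill_2016", "rs6459480", 5.00e-10, -0.01, -0.02, 0.01, be, 0.70, "measurement"),
    list("ATXN1", "educational attainment", "Lee_2018", "rs9297016", 1.00e-9, -0.01, -0.01, 0.006, be, 0.68, "measurement"),
    list("ATXN1", "educational attainment: years of education", "Okbay_2016", "rs7772172", 1.00e-8, -0.01, -0.02, 0.01, be, 0.68, "measurement"),
    list("ATXN1", "educational attainment (years of education)", "Lee_2018", "rs909788", 4.00e-8, -0.01, -0.011, 0.005, be, 0.77, "measurement"),
    list("ATXN1", "central corneal thickness", "Choquet_2020", "rs6459472", 3.00e-9, NA, NA, NA, NA, 0.72, "measurement"),
    list("ATXN1", "male-pattern baldness", "Yap_2018", "rs6915310", 5.00e-20, 0.04, 0.03, 0.05, be, 0.72, "measurement"),
    list("ATXN1", "balding type 1", "Kichaev_2019", "rs9367926", 6.00e-12, NA, NA, NA, NA, 0.71, "measurement"),
    list("ATXN1", "subcutaneous adipose tissue attenuation", "Chu_2021", "rs2237199", 1.00e-8, 5.67, 3.73, 7.61, be, 0.57, "measurement"),
    list("ATXN1", "atrial fibrillation", "Nielsen_2018", "rs73366713", 1.53e-25, 0.90, 0.88, 0.92, or, 0.55, "disease"),
    list("ATXN1", "atrial fibrillation", "Roselli_2018", "rs7770062", 9.00e-21, 0.90, 0.88, 0.92, or, 0.54, "disease"),
    list("ATXN1", "breast cancer", "Michailidou_2017", "rs3819405", 1.65e-8, 0.96, 0.95, 0.97, or, 0.53, "disease"),
    list("ATXN2", "celiac disease", "Dubois_2010", "rs653178", 6.00e-14, 0.83, 0.78, 0.87, or, 0.51, "disease"),
    list("ATXN2", "type 1 diabetes", "Chiou_2021", "rs848130", 1.60e-14, 0.85, 0.82, 0.89, or, 0.67, "disease"),
    list("ATXN7", "schizophrenia", "Lam_2019", "rs832190", 4.00e-8, NA, NA, NA, NA, 0.51, "disease"),
    list("ATXN7", "breast cancer", "Michailidou_2017", "rs3821902", 2.99e-12, 1.06, 1.05, 1.08, or, 0.54, "disease"),
    list("ATXN7", "type 2 diabetes", "Vujkovic_2020", "rs13434089", 4.00e-31, -0.06, -0.07, 0.05, be, 0.55, "disease"),
    list("CACNA1A", "appendicular lean mass", "Pei_2020", "rs5021328", 6.60e-9, -0.01, -0.02, 0.01, be, 0.86, "measurement"),
    list("CACNA1A", "positive affect", "Baselmans_2019", "rs16003", 3.00e-8, 0.01, 0.00, 0.01, be, 0.84, "measurement"),
    list("CACNA1A", "depressive symptoms", "Baselmans_2019", "rs16003", 3.00e-8, 0.01, 0.00, 0.01, be, 0.84, "measurement"),
    list("HTT", "noncognitive aspects of educational attainment", "Demange_2021", "rs363096", 1.00e-12, 0.05, 0.04, 0.06, be, 0.72, "measurement"),
    list("HTT", "educational attainment: years of education", "Kichaev_2019", "rs363096", 1.00e-10, NA, NA, NA, NA, 0.74, "measurement"),
    list("HTT", "depression", "Howard_2019", "rs7685686", 6.00e-15, 0.983, 0.979, 0.987, or, 0.59, "disease"),
    list("HTT", "frailty index", "Atkins_2021", "rs82334", 3.10e-10, -0.02, -0.03, 0.02, be, 0.54, "measurement"),
    list("HTT", "parental lifespan", "Timmers_2019", "rs61348208", 6.00e-9, 0.23, 0.15, 0.31, be, 0.63, "measurement"),
    list("HTT", "gastroesophageal reflux disease", "Ong_2019", "rs7685686", 1.10e-8, 0.97, 0.96, 0.98, or, 0.54, "disease"),
    list("HTT", "aging traits: health span, parental lifespan or longevity", "Timmers_2020", "rs61348208", 3.00e-8, NA, NA, NA, NA, 0.62, "measurement"),
    list("HTT", "vertex-wise sulcal depth", "vanderMeer_2021", "rs2071703", 3.00e-8, 5.57, 3.60, 7.54, be, 0.60, "measurement"),
    list("HTT", "highest math class taken", "Lee_2018", "rs113928896", 2.00e-9, 0.02, 0.01, 0.02, be, 0.55, "measurement"),
    list("HTT", "automobile speeding propensity", "KarlssonLinner_2019", "rs362307", 6.00e-14, -0.03, -0.04, 0.02, be, 0.51, "measurement"),
    list("HTT", "worry/vulnerability: special factor of neuroticism", "Hill_2019", "rs362307", 1.00e-9, 0.01, 0.005, 0.011, be, 0.54, "measurement"),
    list("HTT", "walking pace", "Timmins_2020", "rs362307", 1.00e-9, -0.01, -0.02, 0.01, be, 0.54, "measurement"),
    list("HTT", "type 2 diabetes", "Mahajan_2018", "rs362307", 1.00e-9, 1.08, 1.05, 1.11, or, 0.54, "disease"),
    list("HTT", "predicted visceral adipose tissue", "Karlsson_2019", "rs362307", 2.00e-9, 0.03, 0.02, 0.04, be, 0.54, "measurement"),
    list("HTT", "monobrow", "Pickrell_2016", "rs6828882", 1.00e-22, NA, NA, NA, NA, 0.53, "measurement"),
    list("HTT", "metabolic biomarkers", "Martin_2021", "rs2798297", 1.00e-24, NA, NA, NA, NA, 0.52, "measurement")
  )
  tibble(
    gene_symbol = vapply(rows, function(r) r[[1]], character(1)),
    trait_label = vapply(rows, function(r) r[[2]], character(1)),
    study_id = vapply(rows, function(r) r[[3]], character(1)),
    variant_id = vapply(rows, function(r) r[[4]], character(1)),
    gwas_p = vapply(rows, function(r) r[[5]], double(1)),
    effect = vapply(rows, function(r) as.double(r[[6]] %||% NA_real_), double(1)),
    effect_ci_low = vapply(rows, function(r) as.double(r[[7]] %||% NA_real_), double(1)),
    effect_ci_high = vapply(rows, function(r) as.double(r[[8]] %||% NA_real_), double(1)),
    effect_type = vapply(rows, function(r) if (is.null(r[[9]]) || is.na(r[[9]])) NA_character_ else r[[9]], character(1)),
    l2g = vapply(rows, function(r) r[[10]], double(1)),
    trait_category = vapply(rows, function(r) r[[11]], character(1))
  )
}

table1_variant_annotations <- function() {
  v <- function(id, cons, cadd, allele, af, splice = FALSE, eqtl = NA_character_) {
    tibble(variant_id = id, consequence = cons, cadd = cadd,
           effect_allele = allele, eur_af = af, splice_flag = splice,
           eqtl_gene_ids = eqtl)
  }
  dplyr::bind_rows(
    v("rs719316", "intron_variant", 5.92, "T", 0.529),
    v("rs17603856", "intron_variant", 10.94, "G", 0.346),
    v("rs6459480", "intron_variant", 1.82, "A", 0.509, eqtl = "ENSG00000124788"),
    v("rs9297016", "intron_variant", 2.57, "G", 0.576),
    v("rs7772172", "intron_variant", 5.02, "G", 0.576),
    v("rs909788", "intron_variant", 5.75, "C", 0.545, eqtl = "ENSG00000124788"),
    v("rs6459472", "intron_variant", 2.97, "G", 0.573),
    v("rs6915310", "intron_variant", 4.27, "T", 0.182),
    v("rs9367926", "intron_variant", 6.59, "G", 0.180),
    v("rs2237199", "intron_variant", 3.49, "A", 0.112),
    v("rs73366713", "intron_variant", 2.84, "A", 0.131),
    v("rs7770062", "intron_variant", 2.33, "A", 0.131),
    v("rs3819405", "intron_variant", 12.10, "T", 0.340),
    v("rs653178", "intron_variant", 1.59, "T", 0.534),
    v("rs848130", "intron_variant", 2.02, "A", 0.192),
    v("rs832190", "intron_variant", 0.58, "T", 0.603),
    v("rs3821902", "intron_variant", 0.81, "G", 0.150),
    v("rs13434089", "intron_variant", 4.59, "C", 0.141),
    v("rs5021328", "intron_variant", 0.63, "C", 0.644),
    v("rs16003", "intron_variant", 8.26, "T", 0.463),
    v("rs363096", "splice_region_variant", 6.29, "C", 0.591, splice = TRUE),
    v("rs7685686", "intron_variant", 6.39, "G", 0.433),
    v("rs82334", "intron_variant", 4.13, "C", 0.323),
    v("rs61348208", "intron_variant", 5.46, "T", 0.389),
    v("rs2071703", "intron_variant", 2.52, "C", 0.325),
    v("rs113928896", "intron_variant", 0.32, "T", 0.143),
    v("rs362307", "3_prime_UTR_variant", 3.23, "T", 0.063),
    v("rs6828882", "intron_variant", 8.54, "G", 0.101),
    v("rs2798297", "intron_variant", 2.08, "A", 0.353)
  )
}

#' Build the packaged high-confidence association fixture
#'
#' Returns the 38-row catalog of high-confidence, peer-reviewed GWAS trait
#' associations linked to five polyQ disorder genes (ATXN1, ATXN2, ATXN7,
#' CACNA1A, HTT) over 29 distinct index variants, the per-variant
#' annotations, synthetic per-gene block-LD matrices consistent with the
#' 21-haplotype grouping (within-block r^2 around 0.8, between-block around
#' 0.1), and the expected haplotype table itself.
#'
#' Genomic positions, study identifiers and PubMed ids are synthetic
#' placeholders; positions are assigned so haplotype blocks are contiguous
#' and each block's tag variant comes first.
#'
#' @param ld_seed Seed for the synthetic LD jitter.
#' @return A list with `associations`, `annotations`, `ld_by_gene` (named
#'   list of [ld_matrix()]), and `haplotypes` (expected grouping with
#'   `gene_symbol`, `haplotype_index`, `tag_variant`, `member_variants`).
#' @export
build_table1_fixture <- function(ld_seed = 20240117L) {
  meta <- table1_gene_meta()
  posmap <- table1_variant_positions()
  rows <- table1_rows()
  studies <- sort(unique(rows$study_id), method = "radix")  # locale-independent
  pm <- setNames(sprintf("PM%06d", 100001 + seq_along(studies) - 1), studies)
  associations <- rows |>
    dplyr::left_join(meta[, c("gene_symbol", "gene_id", "chrom")],
                     by = "gene_symbol") |>
    dplyr::left_join(posmap[, c("gene_symbol", "variant_id", "pos")],
                     by = c("gene_symbol", "variant_id")) |>
    dplyr::mutate(
      pubmed_id = unname(pm[.data$study_id]),
      source = "GWAS_catalog",
      ancestries = "EUR"
    )
  associations <- associations[, ASSOCIATION_COLUMNS]
  members <- table1_haplotype_members()
  ld_by_gene <- purrr::imap(members, function(haps, g) {
    ids <- unlist(haps)
    spec <- ld_block_spec(block_sizes = lengths(haps),
                          within_r2 = 0.8, between_r2 = 0.1,
                          r2_cutoff = 0.5,
                          seed = ld_seed + match(g, names(members)))
    generate_ld_blocks(spec, variant_ids = ids)
  })
  haplotypes <- posmap |>
    dplyr::distinct(.data$gene_symbol, .data$haplotype_index, .data$tag) |>
    dplyr::rename(tag_variant = "tag")
  haplotypes$member_variants <- purrr::map2(
    haplotypes$gene_symbol, haplotypes$haplotype_index,
    function(g, h) members[[g]][[h]]
  )
  list(associations = associations,
       annotations = table1_variant_annotations(),
       ld_by_gene = ld_by_gene,
       haplotypes = haplotypes)
}

results_feature_profiles <- function() {
  # classifications: interactions unfavorable for all but THAP11; AR tissue
  # enhanced and CACNA1A tissue enriched (others broadly expressed);
  # constraint unfavorable for five genes. Numeric values are synthetic but
  # consistent with those classifications; the fifth constrained gene is
  # assigned to CACNA1A (a fixture assumption -- the aggregate mean score is
  # invariant to which of the non-named genes it is).
  genes <- tibble(
    gene_symbol = c("AR", "ATN1", "ATXN1", "ATXN2", "ATXN3",
                    "ATXN7", "CACNA1A", "HTT", "TBP", "THAP11"),
    pli = c(0.27, 0.98, 1.00, 0.54, 0.09, 0.97, 1.00, 1.00, 0.88, 0.62),
    oe_lof = c(0.53, 0.13, 0.05, 0.42, 0.74, 0.18, 0.07, 0.10, 0.35, 0.48),
    tissue_class = c("tissue_enhanced", "low_tissue_specificity",
                     "low_tissue_specificity", "low_tissue_specificity",
                     "low_tissue_specificity", "low_tissue_specificity",
                     "tissue_enriched", "low_tissue_specificity",
                     "low_tissue_specificity", "low_tissue_specificity"),
    druggable_any = c(TRUE, FALSE, TRUE, TRUE, FALSE,
                      FALSE, TRUE, TRUE, FALSE, FALSE)
  )
  hi_counts <- c(AR = 32L, ATN1 = 108L, ATXN1 = 112L, ATXN2 = 45L,
                 ATXN3 = 104L, ATXN7 = 28L, CACNA1A = 15L, HTT = 120L,
                 TBP = 24L, THAP11 = 8L)
  interactions <- purrr::imap(hi_counts, function(k, g) {
    j <- seq_len(k + 3L)
    tibble(
      gene_symbol = g,
      partner = sprintf("%s_P%03d", g, j),
      # first k partners above the 0.42 confidence cutoff, last 3 below it
      mi_score = c(round(0.43 + 0.005 * ((j[seq_len(k)] - 1) %% 80), 3),
                   rep(0.30, 3))
    )
  })
  gene_features(genes, dplyr::bind_rows(interactions))
}

results_provenance_catalog <- function() {
  gene_counts <- c(ATXN1 = 57L, HTT = 40L, ATXN2 = 35L, ATXN3 = 25L,
                   CACNA1A = 20L, ATXN7 = 18L, TBP = 20L)
  gene_ids <- c(ATXN1 = "ENSG00000124788", HTT = "ENSG00000197386",
                ATXN2 = "ENSG00000204842", ATXN3 = "ENSG00000066427",
                CACNA1A = "ENSG00000141837", ATXN7 = "ENSG00000163635",
                TBP = "ENSG00000112592")
  chroms <- c(ATXN1 = "6", HTT = "4", ATXN2 = "12", ATXN3 = "14",
              CACNA1A = "19", ATXN7 = "3", TBP = "6")
  n <- sum(gene_counts)  # 215
  gene <- rep(names(gene_counts), gene_counts)
  i <- seq_len(n)
  # non-peer-reviewed biobank releases: 4 + 26 + 2 = 32 records
  src <- rep("GWAS_catalog", n)
  src[seq(4, 204, by = 8)] <- "UKB_NealeLab_R2"
  src[c(51, 101, 151, 201)] <- "FinnGen_R6"
  src[c(33, 87)] <- "UKB_SAIGE"
  no_pm <- src != "GWAS_catalog"
  trait_ix <- ((i - 1) %% 149) + 1
  tibble(
    gene_symbol = gene,
    gene_id = unname(gene_ids[gene]),
    trait_label = sprintf("trait %03d", trait_ix),
    trait_category = ifelse(trait_ix %% 5 == 0, "disease", "measurement"),
    study_id = sprintf("RSTD_%03d", i),
    pubmed_id = ifelse(no_pm, NA_character_, sprintf("PM%06d", 200000 + i)),
    source = src,
    l2g = round(0.51 + 0.4 * ((i * 7) %% 100) / 100, 4),
    variant_id = sprintf("rs77%04d", i),
    chrom = unname(chroms[gene]),
    pos = as.integer(1000000L + 500L * i),
    gwas_p = signif(5e-8 * 10^(-(i %% 18)), 3),
    effect = round(0.01 + 0.001 * (i %% 40), 4),
    effect_ci_low = NA_real_,
    effect_ci_high = NA_real_,
    effect_type = "beta",
    ancestries = "EUR"
  )
}

results_omim_entries <- function() {
  e <- function(g, label, mim, inh, cag = FALSE) {
    tibble(gene_symbol = g, phenotype_label = label, mim_number = mim,
           inheritance = inh,
           susceptibility_flag = startsWith(normalize_trait(label),
                                            "susceptibility to"),
           cag_related_flag = cag)
  }
  dplyr::bind_rows(
    e("AR", "androgen insensitivity, partial, with or without breast cancer",
      "312300", "X-linked recessive"),
    e("AR", "androgen insensitivity", "300068", "X-linked recessive"),
    e("AR", "hypospadias 1, X-linked", "300633", "X-linked recessive"),
    e("AR", "susceptibility to: prostate cancer", "176807",
      "autosomal dominant, somatic mutation"),
    e("ATN1", "congenital hypotonia, epilepsy, developmental delay, and digital anomalies",
      "618494", "autosomal dominant"),
    e("ATXN2", "susceptibility to: amyotrophic lateral sclerosis", "183090",
      "autosomal dominant", cag = TRUE),
    e("ATXN2", "susceptibility to: Parkinson disease, late-onset", "168600",
      "autosomal dominant, multifactorial", cag = TRUE),
    e("CACNA1A", "developmental and epileptic encephalopathy 42", "617106",
      "autosomal dominant"),
    e("CACNA1A", "episodic ataxia, type 2", "108500", "autosomal dominant",
      cag = TRUE),
    e("CACNA1A", "migraine, familial hemiplegic, 1, with progressive cerebellar ataxia",
      "141500", "autosomal dominant"),
    e("HTT", "Lopes-Maciel-Rodan syndrome", "617435", "autosomal recessive"),
    e("TBP", "susceptibility to: Parkinson disease", "168600",
      "autosomal dominant, multifactorial", cag = TRUE)
  )
}

results_study_ancestry <- function() {
  tibble(
    study_id = sprintf("ANC_%02d", 1:41),
    ancestries = c(rep("EUR", 31),
                   rep("EAS;EUR", 5),
                   "AFR;EUR",
                   rep("AFR;EAS;EUR", 3),
                   "AFR;EAS")
  )
}

#' Build the packaged gene-level result fixtures
#'
#' Returns the fixtures encoding the gene-level classification facts of the
#' study: a 215-record provenance catalog (32 of which -- 4 FinnGen_R6, 26
#' UKB_NealeLab_R2, 2 UKB_SAIGE -- lack a PubMed id), the 10-gene feature
#' profile set (only THAP11 at or below 10 high-confidence interactors; AR
#' tissue enhanced and CACNA1A tissue enriched with all other genes broadly
#' expressed; five constraint-unfavorable genes including ATN1, ATXN1,
#' ATXN7, and HTT), the 12-entry OMIM-style phenotype table, and a 41-study
#' ancestry table (31 exclusively European).
#'
#' @return A list with `catalog`, `features` (a [gene_features()] object),
#'   `omim`, and `study_ancestry` tibbles.
#' @export
build_results_fixtures <- function() {
  list(
    catalog = results_provenance_catalog(),
    features = results_feature_profiles(),
    omim = results_omim_entries(),
    study_ancestry = results_study_ancestry()
  )
}

#' Write the packaged fixtures as TSV files
#'
#' Regenerates every shipped fixture table (`inst/extdata/`) from the
#' builders; the shipped files are bit-identical to this output.
#'
#' @param dir Output directory (created if needed).
#' @param ld_seed Seed forwarded to [build_table1_fixture()].
#' @return Invisibly, the vector of written paths.
#' @export
write_fixture_files <- function(dir, ld_seed = 20240117L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  t1 <- build_table1_fixture(ld_seed)
  res <- build_results_fixtures()
  paths <- c(
    associations = file.path(dir, "table1_associations.tsv"),
    annotations = file.path(dir, "table1_annotations.tsv"),
    haplotypes = file.path(dir, "table1_haplotypes.tsv"),
    catalog = file.path(dir, "results_provenance_catalog.tsv"),
    features = file.path(dir, "results_gene_features.tsv"),
    interactions = file.path(dir, "results_gene_interactions.tsv"),
    omim = file.path(dir, "results_omim_entries.tsv"),
    ancestry = file.path(dir, "results_study_ancestry.tsv")
  )
  write_association_table(t1$associations, paths[["associations"]])
  write_annotation_table(t1$annotations, paths[["annotations"]])
  readr::write_tsv(flatten_haplotypes(t1$haplotypes)[
    , c("gene_symbol", "haplotype_index", "tag_variant", "member_variants")],
    paths[["haplotypes"]], na = ".", progress = FALSE)
  for (g in names(t1$ld_by_gene)) {
    p <- file.path(dir, sprintf("table1_ld_%s.tsv", tolower(g)))
    write_ld_matrix(t1$ld_by_gene[[g]], p)
    paths[[paste0("ld_", g)]] <- p
  }
  write_association_table(res$catalog, paths[["catalog"]])
  readr::write_tsv(res$features$genes, paths[["features"]], na = ".", progress = FALSE)
  readr::write_tsv(res$features$interactions, paths[["interactions"]],
                   na = ".", progress = FALSE)
  write_omim_table(res$omim, paths[["omim"]])
  readr::write_tsv(res$study_ancestry, paths[["ancestry"]], na = ".", progress = FALSE)
  invisible(paths)
}

#' Path to a shipped fixture file
#'
#' @param file File name under the package's `extdata/` directory.
#' @return Absolute path to the installed fixture file.
#' @export
fixture_path <- function(file) {
  system.file("extdata", file, package = "polyqprofiler", mustWork = TRUE)
}
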