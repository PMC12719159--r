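test_that("catalog generator is deterministic and honours its mixes", {
  spec <- catalog_spec(n_genes = 4, traits_per_gene = 12, provenance_mix = 0.2,
                       shared_trait_pairs = list(list("G1", "G2", 3)), seed = 7)
  a <- generate_catalog(spec)
  b <- generate_catalog(spec)
  expect_identical(a, b)

  # planted sharing is exact: the network stage recovers edge weight 3
  net <- build_network(a)
  e <- net$edges[net$edges$gene_a == "G1" & net$edges$gene_b == "G2", ]
  expect_equal(e$weight, 3L)
  # and no sharing arises outside the planted pair
  expect_equal(nrow(net$edges), 1)

  all_pm <- generate_catalog(catalog_spec(n_genes = 3, traits_per_gene = 8,
                                          provenance_mix = 0, seed = 3))
  expect_false(anyNA(all_pm$pubmed_id))

  # realized missing-pubmed fraction stays within binomial sampling error
  big <- generate_catalog(catalog_spec(n_genes = 20, traits_per_gene = 30,
                                       provenance_mix = 0.15, seed = 5))
  frac <- mean(is.na(big$pubmed_id))
  expect_lt(abs(frac - 0.15), 4 * sqrt(0.15 * 0.85 / nrow(big)))

  expect_error(
    generate_catalog(catalog_spec(n_genes = 2, traits_per_gene = 2,
                                  shared_trait_pairs = list(list("G1", "G2", 5)))),
    class = "polyq_spec_error")
})

test_that("block LD generator straddles the pruning cutoff deterministically", {
  spec <- ld_block_spec(block_sizes = c(2, 3), within_r2 = 0.9,
                        between_r2 = 0.1, seed = 42)
  m <- generate_ld_blocks(spec)
  expect_identical(m, generate_ld_blocks(spec))
  vars <- tibble::tibble(variant_id = rownames(m), pos = seq_len(5),
                         gwas_p = rep(1e-8, 5))
  haps <- prune_to_haplotypes(vars, m, 0.5)
  expect_equal(nrow(haps), 2)
  expect_equal(sort(lengths(haps$member_variants)), c(2, 3))

  one <- generate_ld_blocks(ld_block_spec(block_sizes = 1, seed = 1))
  expect_equal(dim(unclass(one)), c(1, 1))

  # boundary: within-block r2 barely above the cutoff still recovers blocks
  tight <- generate_ld_blocks(ld_block_spec(block_sizes = c(3, 2),
                                            within_r2 = 0.51, between_r2 = 0.1,
                                            r2_cutoff = 0.5, seed = 9))
  expect_true(all(unclass(tight)[1:3, 1:3] > 0.5))
  vars <- tibble::tibble(variant_id = rownames(tight), pos = 1:5,
                         gwas_p = rep(1e-8, 5))
  expect_equal(nrow(prune_to_haplotypes(vars, tight, 0.5)), 2)
})

test_that("shipped fixture files regenerate bit-identically from the builders", {
  dir <- withr::local_tempdir()
  paths <- write_fixture_files(dir)
  for (p in paths) {
    shipped <- fixture_path(basename(p))
    expect_identical(readLines(p), readLines(shipped), label = basename(p))
  }
})

test_that("fixture encodes the study's per-gene classification facts", {
  res <- build_results_fixtures()
  expect_equal(sum(is.na(res$catalog$pubmed_id)), 32)
  expect_equal(nrow(res$catalog), 215)
  expect_equal(length(unique(normalize_trait(res$catalog$trait_label))), 149)
  expect_equal(sum(res$catalog$gene_symbol == "ATXN1"), 57)
  expect_true(all(res$catalog$l2g > 0.5))

  pc <- count_partners(res$features, mi_cutoff = 0.42)
  expect_lte(pc$interaction_partner_count[pc$gene_symbol == "THAP11"], 10)
  expect_true(all(pc$interaction_partner_count[pc$gene_symbol != "THAP11"] > 10))

  g <- res$features$genes
  expect_equal(g$tissue_class[g$gene_symbol == "AR"], "tissue_enhanced")
  expect_equal(g$tissue_class[g$gene_symbol == "CACNA1A"], "tissue_enriched")
  expect_equal(sum(g$tissue_class == "low_tissue_specificity"), 8)
  constrained <- g$gene_symbol[g$pli > 0.9]
  expect_length(constrained, 5)
  expect_true(all(c("ATN1", "ATXN1", "ATXN7", "HTT") %in% constrained))
  expect_equal(sum(g$druggable_any), 5)
})

test_that("association fixture carries the printed per-variant values", {
  t1 <- build_table1_fixture()
  rec <- t1$associations[t1$associations$variant_id == "rs719316", ]
  expect_equal(rec$l2g, 0.79)
  ann <- t1$annotations[t1$annotations$variant_id == "rs719316", ]
  expect_equal(ann$cadd, 5.92)
  expect_equal(ann$consequence, "intron_variant")

  celiac <- t1$associations[t1$associations$variant_id == "rs653178", ]
  expect_equal(celiac$trait_label, "celiac disease")
  expect_equal(celiac$effect_type, "odds_ratio")

  atxn1 <- t1$associations[t1$associations$gene_symbol == "ATXN1", ]
  expect_equal(length(unique(atxn1$variant_id)), 13)
})
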