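test_that("count-trait flagging matches the pattern list and partitions exactly", {
  cat <- random_catalog(4, seed = 8)
  cat$trait_label <- c("neutrophil count", "educational attainment",
                       "Reticulocyte fraction", "type 2 diabetes")
  out <- flag_count_traits(cat)
  expect_setequal(out$removed$trait_label,
                  c("neutrophil count", "Reticulocyte fraction"))
  expect_equal(nrow(out$kept) + nrow(out$removed), nrow(cat))
  expect_identical(dplyr::bind_rows(out$kept, out$removed)[order(
    match(dplyr::bind_rows(out$kept, out$removed)$study_id, cat$study_id)), ]$study_id,
    cat$study_id)

  none <- flag_count_traits(cat, character(0))
  expect_equal(nrow(none$removed), 0)

  expect_error(flag_count_traits(cat, "("), class = "polyq_config_error")
})

test_that("peer-review filter keys on pubmed presence and tallies by source", {
  cat <- random_catalog(10, seed = 13)
  cat$pubmed_id <- sprintf("PM%d", 1:10)
  out <- filter_peer_reviewed(cat)
  expect_equal(nrow(out$removed), 0)

  cat$pubmed_id[4] <- NA
  cat$source[4] <- "FinnGen_R6"
  out <- filter_peer_reviewed(cat)
  expect_equal(out$report$n_removed_non_pubmed, 1)
  expect_equal(out$report$removed_by_source, c(FinnGen_R6 = 1L))
  expect_equal(out$report$n_in, out$report$n_retained + 1)

  solo <- filter_peer_reviewed(cat[4, ])
  expect_equal(solo$report$pct_removed, 100)
})

test_that("trait deduplication keeps the max-L2G record with canonical tie-breaks", {
  base <- random_catalog(3, seed = 5)
  base$gene_symbol <- "G1"
  base$trait_label <- "height"
  base$l2g <- c(0.6, 0.8, 0.7)
  kept <- dedup_traits(base)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$l2g, 0.8)

  two_genes <- base[1:2, ]
  two_genes$gene_symbol <- c("G1", "G2")
  expect_equal(nrow(dedup_traits(two_genes)), 2)

  tie <- base
  tie$l2g <- 0.7
  tie$gwas_p <- 1e-9
  tie$variant_id <- c("rs300", "rs100", "rs200")
  expect_equal(dedup_traits(tie)$variant_id, "rs100")

  # invariance to input order
  big <- random_catalog(50, seed = 17)
  shuffled <- big[sample.int(nrow(big)), ]
  expect_equal(as.data.frame(dedup_traits(big)),
               as.data.frame(dedup_traits(shuffled)))
})

test_that("ancestry summaries count per study, not per record", {
  rec <- tibble::tibble(study_id = c("s1", "s2"),
                        ancestries = c("EUR", "EAS;EUR"))
  s <- summarize_ancestry(rec)
  expect_equal(s$n_exclusive[["EUR"]], 1)
  expect_equal(s$n_any[["EUR"]], 2)

  triple <- tibble::tibble(study_id = rep("s1", 3), ancestries = rep("EUR", 3))
  expect_equal(summarize_ancestry(triple)$n_studies, 1)

  anc <- build_results_fixtures()$study_ancestry
  s <- summarize_ancestry(anc)
  expect_equal(s$n_studies, 41)
  expect_equal(s$pct_exclusive[["EUR"]], 75.6)
  expect_equal(s$pct_any[["EUR"]], 97.6)
  expect_equal(s$pct_any[["EAS"]], 22.0)
  expect_equal(s$pct_any[["AFR"]], 12.2)
})

test_that("OMIM classification partitions entries and tallies CAG relation", {
  omim <- build_results_fixtures()$omim
  cls <- classify_omim_entries(omim)
  expect_equal(cls$mendelian + cls$susceptibility, cls$n_entries)

  empty <- classify_omim_entries(omim[0, ])
  expect_equal(empty$mendelian, 0)
  expect_equal(empty$susceptibility, 0)
  expect_equal(empty$cag_related, 0)
})

test_that("full prioritization bookkeeping is partition-exact", {
  cat <- random_catalog(60, seed = 19)
  cat$trait_label[1:10] <- sprintf("platelet count %d", 1:10)
  out <- prioritize_catalog(cat)
  r <- out$report
  expect_equal(r$n_in, r$n_retained + r$n_removed_count_traits + r$n_removed_non_pubmed)
  expect_equal(sum(r$removed_by_source), r$n_removed_non_pubmed)
  expect_lte(r$n_unique_after_dedup, r$n_retained)
})
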