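make_ld <- function(ids, fill = 0) {
  m <- matrix(fill, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 1
  m
}

test_that("consequence severity ranking resolves the most severe term", {
  expect_equal(most_severe("intron_variant"), "intron_variant")
  expect_equal(most_severe(c("intron_variant", "splice_region_variant")),
               "splice_region_variant")
  expect_equal(most_severe(c("3_prime_UTR_variant", "intron_variant")),
               "3_prime_UTR_variant")
  expect_error(most_severe("made_up_term"), "made_up_term",
               class = "polyq_validation_error")
})

test_that("pruning handles trivial topologies", {
  v1 <- tibble::tibble(variant_id = "rs1", pos = 1L, gwas_p = 1e-9)
  h <- prune_to_haplotypes(v1, ld_matrix(make_ld("rs1")), 0.5)
  expect_equal(h$tag_variant, "rs1")
  expect_equal(h$member_variants[[1]], "rs1")

  ids <- paste0("rs", 1:4)
  m <- make_ld(ids, fill = 0.9)
  vars <- tibble::tibble(variant_id = ids, pos = 1:4, gwas_p = rep(1e-9, 4))
  h <- prune_to_haplotypes(vars, ld_matrix(m), 0.5)
  expect_equal(nrow(h), 1)
  expect_equal(h$n_members, 4L)

  expect_error(
    prune_to_haplotypes(tibble::tibble(variant_id = "rsX", pos = 1L, gwas_p = 1e-9),
                        ld_matrix(make_ld("rs1")), 0.5),
    "rsX", class = "polyq_validation_error")
})

test_that("missing LD entries are treated as independence with a warning", {
  ids <- c("rs1", "rs2")
  m <- make_ld(ids)
  m["rs1", "rs2"] <- NA; m["rs2", "rs1"] <- NA
  vars <- tibble::tibble(variant_id = ids, pos = 1:2, gwas_p = rep(1e-9, 2))
  expect_warning(h <- prune_to_haplotypes(vars, ld_matrix(m), 0.5),
                 class = "polyq_missing_ld_warning")
  expect_equal(nrow(h), 2)
})

test_that("chain LD follows the tag-centric rule, not single linkage", {
  # a-b and b-c in LD but a-c not: the greedy rule seeds at a, absorbs b,
  # and leaves c as its own haplotype; single linkage would merge all three
  ids <- c("a", "b", "c")
  m <- make_ld(ids, fill = 0.1)
  m["a", "b"] <- m["b", "a"] <- 0.9
  m["b", "c"] <- m["c", "b"] <- 0.9
  vars <- tibble::tibble(variant_id = ids, pos = 1:3, gwas_p = rep(1e-9, 3))
  h <- prune_to_haplotypes(vars, ld_matrix(m), 0.5)
  expect_equal(nrow(h), 2)
  expect_equal(h$member_variants[[1]], c("a", "b"))
  expect_equal(h$member_variants[[2]], "c")
  expect_equal(length(oracle_single_linkage(m, ids, 0.5)), 1)
})

test_that("pruning partitions the variants and satisfies the LD invariants", {
  for (seed in 1:20) {
    set.seed(seed)
    sizes <- sample(1:4, sample(1:4, 1), replace = TRUE)
    m <- generate_ld_blocks(ld_block_spec(sizes, within_r2 = 0.8,
                                          between_r2 = 0.1, seed = seed))
    ids <- rownames(m)
    vars <- tibble::tibble(variant_id = ids, pos = seq_along(ids),
                           gwas_p = stats::runif(length(ids), 1e-12, 1e-8))
    h <- prune_to_haplotypes(vars, m, 0.5)
    members <- unlist(h$member_variants)
    expect_setequal(members, ids)
    expect_equal(anyDuplicated(members), 0)
    # within: every member in LD with its tag; across: tags independent
    for (r in seq_len(nrow(h))) {
      tag <- h$tag_variant[r]
      for (v in setdiff(h$member_variants[[r]], tag)) {
        expect_gt(unclass(m)[tag, v], 0.5)
      }
    }
    tags <- h$tag_variant
    if (length(tags) > 1) {
      expect_true(all(unclass(m)[tags, tags][upper.tri(diag(length(tags)))] <= 0.5))
    }
  }
})

test_that("pruning is invariant to input row order", {
  m <- generate_ld_blocks(ld_block_spec(c(3, 2, 4), seed = 31))
  ids <- rownames(m)
  vars <- tibble::tibble(variant_id = ids, pos = seq_along(ids),
                         gwas_p = seq_along(ids) * 1e-9)
  h1 <- prune_to_haplotypes(vars, m, 0.5)
  set.seed(1)
  h2 <- prune_to_haplotypes(vars[sample.int(nrow(vars)), ], m, 0.5)
  expect_identical(h1, h2)
})

test_that("pruning matches the independent greedy oracle on random LD patterns", {
  for (seed in 1:50) {
    set.seed(seed)
    n <- sample(2:6, 1)
    ids <- paste0("rs", seq_len(n))
    m <- make_ld(ids)
    vals <- sample(c(0, 0.9), n * (n - 1) / 2, replace = TRUE)
    m[upper.tri(m)] <- vals
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    vars <- tibble::tibble(variant_id = ids, pos = seq_len(n),
                           gwas_p = rep(1e-9, n))
    h <- prune_to_haplotypes(vars, ld_matrix(m), 0.5)
    oracle <- oracle_greedy_prune(m, ids, 0.5)
    expect_equal(nrow(h), length(oracle))
    expect_equal(sort(h$tag_variant),
                 sort(vapply(oracle, function(cl) cl$tag, character(1))))
  }
})

test_that("trait assignment attaches every record to its variant's haplotype", {
  t1 <- build_table1_fixture()
  haps <- identify_signals(t1$associations, t1$ld_by_gene, 0.5)
  expect_equal(sum(haps$n_traits), nrow(t1$associations))

  stray <- t1$associations[1, ]
  stray$variant_id <- "rs_not_in_ld"
  expect_error(assign_traits(stray, haps), "rs_not_in_ld",
               class = "polyq_validation_error")
})

test_that("haplotype recovery matches the packaged expected grouping", {
  t1 <- build_table1_fixture()
  haps <- identify_signals(t1$associations, t1$ld_by_gene, 0.5)
  expected <- t1$haplotypes
  got <- haps[order(haps$gene_symbol, haps$haplotype_index), ]
  exp <- expected[order(expected$gene_symbol, expected$haplotype_index), ]
  expect_equal(got$tag_variant, exp$tag_variant)
  expect_equal(lapply(got$member_variants, sort),
               lapply(exp$member_variants, sort))
})
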