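test_that("feature classifiers apply strict thresholds with unknown for missing", {
  expect_equal(classify_constraint(c(1.0, 0.9, NA)),
               c("unfavorable", "favorable", "unknown"))

  res <- build_results_fixtures()$features
  g <- res$genes
  expect_equal(classify_expression(g$tissue_class[g$gene_symbol == "AR"]),
               "favorable")
  expect_equal(classify_expression(g$tissue_class[g$gene_symbol == "HTT"]),
               "unfavorable")
  expect_equal(classify_expression("not_detected"), "favorable")
  expect_error(classify_expression("everywhere"), class = "polyq_validation_error")

  # partner counting respects the MI cutoff before the partner cutoff
  eleven <- gene_features(
    tibble::tibble(gene_symbol = "X", pli = 0.1, oe_lof = 1,
                   tissue_class = "not_detected", druggable_any = FALSE),
    tibble::tibble(gene_symbol = "X", partner = sprintf("P%02d", 1:11),
                   mi_score = 0.5))
  expect_equal(classify_interactions(
    count_partners(eleven, 0.42)$interaction_partner_count, 10), "unfavorable")

  fifty_low <- gene_features(
    eleven$genes,
    tibble::tibble(gene_symbol = "X", partner = sprintf("P%02d", 1:50),
                   mi_score = 0.40))
  expect_equal(classify_interactions(
    count_partners(fifty_low, 0.42)$interaction_partner_count, 10), "favorable")
})

test_that("safety scores count unfavorable features and respond monotonically", {
  benign <- gene_features(
    tibble::tibble(gene_symbol = "X", pli = 0.1, oe_lof = 1,
                   tissue_class = "tissue_enriched", druggable_any = TRUE),
    tibble::tibble(gene_symbol = character(), partner = character(),
                   mi_score = double()))
  expect_equal(aggregate_scores(benign)$safety_score, 0L)

  # flipping each feature to unfavorable raises the score by exactly one
  flips <- list(
    function(gf) { gf$genes$pli <- 0.95; gf },
    function(gf) { gf$genes$tissue_class <- "low_tissue_specificity"; gf },
    function(gf) {
      gf$interactions <- tibble::tibble(gene_symbol = "X",
                                        partner = sprintf("P%02d", 1:11),
                                        mi_score = 0.5)
      gf
    })
  state <- benign
  for (k in seq_along(flips)) {
    state <- flips[[k]](state)
    expect_equal(aggregate_scores(state)$safety_score, k)
  }

  # unknown features never contribute
  unknown <- benign
  unknown$genes$pli <- NA
  v <- aggregate_scores(unknown)
  expect_equal(v$constraint, "unknown")
  expect_equal(v$safety_score, 0L)
})

test_that("rank-sum comparison handles degenerate and frozen exact cases", {
  deg <- rank_sum_compare(c(1, 1, 1), c(1, 1, 1))
  expect_equal(deg$z_value, 0)
  expect_equal(deg$p_two_sided, 1)
  expect_equal(deg$effect_r, 0)

  expect_equal(rank_sum_compare(c(1, 2), c(3, 4), method = "exact")$p_two_sided,
               1 / 3)
  expect_equal(rank_sum_compare(c(3, 3, 3), c(0, 0, 0),
                                method = "exact")$p_two_sided, 0.1)

  expect_error(rank_sum_compare(numeric(0), 1), class = "polyq_validation_error")
  expect_error(rank_sum_compare(1:7, 1:6, method = "exact"),
               class = "polyq_validation_error")
})

test_that("rank-sum comparison is symmetric and rank-invariant", {
  set.seed(42)
  for (i in 1:10) {
    a <- sample(0:3, 5, replace = TRUE)
    b <- sample(0:3, 7, replace = TRUE)
    ab <- rank_sum_compare(a, b)
    ba <- rank_sum_compare(b, a)
    expect_equal(ab$z_value, -ba$z_value)
    expect_equal(ab$p_two_sided, ba$p_two_sided)
    expect_equal(ab$effect_r, ba$effect_r)
    # monotone relabeling of the scores leaves the rank-based result alone
    relab <- rank_sum_compare(a * 10 + 2, b * 10 + 2)
    expect_equal(relab$z_value, ab$z_value)
    expect_equal(relab$effect_r, ab$effect_r)
  }
})

test_that("tie-corrected normal p matches the base-R rank-sum test", {
  set.seed(7)
  for (i in 1:10) {
    a <- sample(0:3, 10, replace = TRUE)
    b <- sample(0:3, 9, replace = TRUE)
    if (length(unique(c(a, b))) == 1) next
    mine <- rank_sum_compare(a, b, method = "normal")
    ref <- suppressWarnings(stats::wilcox.test(a, b, correct = FALSE,
                                               exact = FALSE))
    expect_equal(mine$p_two_sided, unname(ref$p.value), tolerance = 1e-12)
    expect_equal(mine$u_statistic, unname(ref$statistic))
  }
})

test_that("normal approximation tracks exact enumeration where it is reliable", {
  # exhaustively frozen bound: over all score-multiset pairs (sizes <= 6,
  # values 0..3) whose exact two-sided p is at most 0.1, the tie-corrected
  # normal p deviates by less than 0.08; tiny tie-heavy groups with large p
  # can deviate far more, which is why the exact method exists
  worst <- 0
  for (na in 2:5) for (nb in na:5) {
    for (a in score_multisets(na)) for (b in score_multisets(nb)) {
      px <- rank_sum_compare(a, b, method = "exact")$p_two_sided
      if (px > 0.1) next
      pn <- rank_sum_compare(a, b, method = "normal")$p_two_sided
      worst <- max(worst, abs(pn - px))
    }
  }
  expect_lt(worst, 0.08)

  # at larger group sizes the normal p agrees with a Monte-Carlo permutation p
  set.seed(11)
  a <- sample(0:3, 20, replace = TRUE, prob = c(1, 2, 3, 2))
  b <- sample(0:3, 20, replace = TRUE, prob = c(3, 2, 1, 1))
  obs <- rank_sum_compare(a, b, method = "normal")
  pooled <- c(a, b)
  mu <- length(a) * length(b) / 2
  u_obs <- obs$u_statistic
  perm <- replicate(20000, {
    ix <- sample.int(40, 20)
    r <- rank(pooled)
    sum(r[ix]) - 20 * 21 / 2
  })
  p_mc <- mean(abs(perm - mu) >= abs(u_obs - mu) - 1e-9)
  expect_lt(abs(obs$p_two_sided - p_mc), 0.02)
})

test_that("gene-set comparison reports fixture means and degenerate identity", {
  res <- build_results_fixtures()$features
  cmp <- compare_gene_sets(res, res)
  expect_equal(cmp$comparison$mean_a, 2.2)
  expect_equal(cmp$comparison$mean_b, 2.2)
  expect_equal(cmp$comparison$p_two_sided, 1)

  hi <- gene_features(
    tibble::tibble(gene_symbol = c("A", "B", "C"), pli = 0.99, oe_lof = 0.1,
                   tissue_class = "low_tissue_specificity", druggable_any = FALSE),
    tibble::tibble(gene_symbol = rep(c("A", "B", "C"), each = 12),
                   partner = sprintf("P%02d", 1:36), mi_score = 0.5))
  lo <- gene_features(
    tibble::tibble(gene_symbol = c("D", "E", "F"), pli = 0.1, oe_lof = 1,
                   tissue_class = "tissue_enriched", druggable_any = TRUE),
    tibble::tibble(gene_symbol = character(), partner = character(),
                   mi_score = double()))
  cmp <- compare_gene_sets(hi, lo, method = "exact")
  expect_equal(cmp$comparison$p_two_sided, 0.1)
  expect_equal(cmp$verdicts_a$safety_score, c(3L, 3L, 3L))
  expect_equal(cmp$verdicts_b$safety_score, c(0L, 0L, 0L))
})
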