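#' Classify genes on genetic constraint
#'
#' A gene is unfavorable as a drug target when extremely intolerant to
#' loss-of-function variation, i.e. pLI strictly greater than the cutoff
#' (default 0.9). Boundary values are favorable; missing pLI is unknown.
#'
#' @param pli Numeric vector of pLI scores (`NA` = missing).
#' @param pli_cutoff Constraint cutoff in `[0,1]`.
#' @return Character vector: `"unfavorable"`, `"favorable"`, or `"unknown"`.
#' @export
classify_constraint <- function(pli, pli_cutoff = 0.9) {
  stopifnot(pli_cutoff >= 0, pli_cutoff <= 1)
  dplyr::case_when(
    is.na(pli) ~ "unknown",
    pli > pli_cutoff ~ "unfavorable",
    TRUE ~ "favorable"
  )
}

#' Classify genes on tissue expression breadth
#'
#' Genes whose Human Protein Atlas RNA specificity class is
#' `"low_tissue_specificity"` are broadly expressed and therefore
#' unfavorable; any other class (tissue enriched/enhanced, group enriched,
#' not detected) is favorable, and a missing class is unknown.
#'
#' @param tissue_class Character vector of HPA classes (`NA` = missing).
#' @return Character vector: `"unfavorable"`, `"favorable"`, or `"unknown"`.
#' @export
classify_expression <- function(tissue_class) {
  known <- is.na(tissue_class) | tissue_class %in% HPA_TISSUE_CLASSES
  if (!all(known)) {
    abort(sprintf("Unknown tissue class(es): %s",
                  paste(unique(tissue_class[!known]), collapse = ", ")),
          class = "polyq_validation_error")
  }
  dplyr::case_when(
    is.na(tissue_class) ~ "unknown",
    tissue_class == "low_tissue_specificity" ~ "unfavorable",
    TRUE ~ "favorable"
  )
}

#' Count high-confidence interaction partners per gene
#'
#' @param profiles A [gene_features()] object.
#' @param mi_cutoff MI-score cutoff; partners count only when their MI score
#'   is strictly greater than this value.
#' @return Tibble with `gene_symbol` and `interaction_partner_count` for
#'   every gene in the profile set (0 when no interaction qualifies).
#' @export
count_partners <- function(profiles, mi_cutoff = 0.42) {
  ix <- profiles$interactions
  hi <- ix[!is.na(ix$mi_score) & ix$mi_score > mi_cutoff, , drop = FALSE]
  counts <- hi |>
    dplyr::distinct(.data$gene_symbol, .data$partner) |>
    dplyr::count(.data$gene_symbol, name = "interaction_partner_count")
  out <- tibble(gene_symbol = profiles$genes$gene_symbol) |>
    dplyr::left_join(counts, by = "gene_symbol")
  out$interaction_partner_count[is.na(out$interaction_partner_count)] <- 0L
  out$interaction_partner_count <- as.integer(out$interaction_partner_count)
  out
}

#' Classify genes on molecular interaction breadth
#'
#' A gene is unfavorable when it has strictly more than `partner_cutoff`
#' interaction partners at high confidence (MI score strictly above
#' `mi_cutoff`); exactly `partner_cutoff` or fewer is favorable.
#'
#' @param partner_count Integer vector of high-confidence partner counts
#'   (see [count_partners()]); `NA` = unknown.
#' @param partner_cutoff Partner-count cutoff (default 10).
#' @return Character vector: `"unfavorable"`, `"favorable"`, or `"unknown"`.
#' @export
classify_interactions <- function(partner_count, partner_cutoff = 10L) {
  dplyr::case_when(
    is.na(partner_count) ~ "unknown",
    partner_count > partner_cutoff ~ "unfavorable",
    TRUE ~ "favorable"
  )
}

#' Aggregate per-gene genomic safety scores
#'
#' Combines the three safety-relevant features associated with clinical
#' trial stoppage -- genetic constraint, broad expression, and many
#' high-confidence interactors -- into a 0-3 safety score per gene (count of
#' unfavorable features; unknown features never contribute). The
#' druggable-any indicator is carried through for reference but never enters
#' the score: it marks theoretical perturbability, not safety. Genes are
#' ranked by descending score, ties broken by gene symbol.
#'
#' @param profiles A [gene_features()] object.
#' @param config A [threshold_config()].
#' @return A tibble with one row per gene: the three per-feature verdicts,
#'   `interaction_partner_count`, `druggable_any`, and `safety_score`.
#' @export
aggregate_scores <- function(profiles, config = threshold_config()) {
  g <- profiles$genes
  pc <- count_partners(profiles, config$mi_cutoff)
  out <- tibble(
    gene_symbol = g$gene_symbol,
    constraint = classify_constraint(g$pli, config$pli_cutoff),
    expression = classify_expression(g$tissue_class),
    interactions = classify_interactions(pc$interaction_partner_count,
                                         config$partner_cutoff),
    interaction_partner_count = pc$interaction_partner_count,
    druggable_any = g$druggable_any
  )
  out$safety_score <- (out$constraint == "unfavorable") +
    (out$expression == "unfavorable") + (out$interactions == "unfavorable")
  out[order(-out$safety_score, out$gene_symbol), , drop = FALSE]
}

# cache of index-subset matrices for exact enumeration (small n only)
combn_cache <- new.env(parent = emptyenv())
cached_combn <- function(n, k) {
  key <- paste(n, k)
  if (!exists(key, envir = combn_cache)) {
    assign(key, utils::combn(n, k), envir = combn_cache)
  }
  get(key, envir = combn_cache)
}

effect_size_label <- function(r) {
  dplyr::case_when(
    r >= 0.5 ~ "large",
    r >= 0.3 ~ "medium",
    r >= 0.1 ~ "small",
    TRUE ~ "negligible"
  )
}

#' Two-sided rank-sum comparison of two score sets
#'
#' Mann-Whitney/Wilcoxon rank-sum test on mid-ranks. The default
#' `"normal"` method uses the tie-corrected variance with no continuity
#' correction; the `"exact"` method enumerates all assignments of the
#' pooled values to groups (feasible for `n_a + n_b <= 12`) and computes
#' the two-sided permutation p-value
#' `P(|U - mu| >= |U_obs - mu|)`. The effect size is `r = |z| / sqrt(n)`
#' with conventional labels at 0.1/0.3/0.5 (negligible/small/medium/large).
#' When all pooled values are identical the comparison is degenerate:
#' `z = 0`, `p = 1`, `r = 0`.
#'
#' @param scores_a,scores_b Numeric vectors (non-empty).
#' @param method `"normal"` (tie-corrected normal approximation) or
#'   `"exact"` (complete enumeration).
#' @return A list of class `comparison_result`: `n_a`, `n_b`, `mean_a`,
#'   `mean_b`, `u_statistic` (U of group a), `z_value`, `p_two_sided`,
#'   `effect_r`, `effect_label`, `method`.
#' @examples
#' rank_sum_compare(c(1, 2), c(3, 4), method = "exact")$p_two_sided  # 1/3
#' @export
rank_sum_compare <- function(scores_a, scores_b, method = c("normal", "exact")) {
  method <- rlang::arg_match(method)
  if (length(scores_a) == 0 || length(scores_b) == 0) {
    abort("Both score groups must be non-empty.", class = "polyq_validation_error")
  }
  n_a <- length(scores_a); n_b <- length(scores_b); n <- n_a + n_b
  pooled <- c(scores_a, scores_b)
  r <- rank(pooled)
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  mu <- n_a * n_b / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- (n_a * n_b / 12) * ((n + 1) - tie_term / (n * (n - 1)))
  degenerate <- sigma2 <= 1e-12
  z <- if (degenerate) 0 else (u - mu) / sqrt(sigma2)
  if (method == "exact") {
    if (n > 12) {
      abort("Exact enumeration limited to n_a + n_b <= 12.",
            class = "polyq_validation_error")
    }
    if (degenerate) {
      p <- 1
    } else {
      combos <- cached_combn(n, n_a)
      us <- colSums(matrix(r[combos], nrow = n_a)) - n_a * (n_a + 1) / 2
      p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    }
    method_label <- "exact_enumeration"
  } else {
    p <- if (degenerate) 1 else min(1, 2 * stats::pnorm(-abs(z)))
    method_label <- "normal_tie_corrected"
  }
  effect_r <- abs(z) / sqrt(n)
  structure(
    list(
      n_a = n_a, n_b = n_b,
      mean_a = mean(scores_a), mean_b = mean(scores_b),
      u_statistic = u, z_value = z, p_two_sided = p,
      effect_r = effect_r, effect_label = effect_size_label(effect_r),
      method = method_label
    ),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s\n", x$method))
  cat(sprintf("  n = %d vs %d | means %.2f vs %.2f | U = %g | z = %.3f\n",
              x$n_a, x$n_b, x$mean_a, x$mean_b, x$u_statistic, x$z_value))
  cat(sprintf("  p (two-sided) = %.4g | effect r = %.3f (%s)\n",
              x$p_two_sided, x$effect_r, x$effect_label))
  invisible(x)
}

#' Compare the safety profiles of two gene sets
#'
#' Scores both gene sets with [aggregate_scores()] and compares the
#' per-gene safety scores with [rank_sum_compare()]. Group means are
#' reported rounded half-up to one decimal.
#'
#' @param profiles_a,profiles_b [gene_features()] objects for the two sets
#'   (e.g. polyQ disorder genes versus disease modifier genes).
#' @param config A [threshold_config()].
#' @param method Passed to [rank_sum_compare()].
#' @return A list with `comparison` (a `comparison_result` whose means are
#'   rounded to 1 d.p.), `verdicts_a`, `verdicts_b`.
#' @export
compare_gene_sets <- function(profiles_a, profiles_b,
                              config = threshold_config(),
                              method = c("normal", "exact")) {
  va <- aggregate_scores(profiles_a, config)
  vb <- aggregate_scores(profiles_b, config)
  cmp <- rank_sum_compare(va$safety_score, vb$safety_score, method = method)
  cmp$mean_a <- round_half_up(cmp$mean_a, 1)
  cmp$mean_b <- round_half_up(cmp$mean_b, 1)
  list(comparison = cmp, verdicts_a = va, verdicts_b = vb)
}
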