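# Independent brute-force oracles used to cross-check the package's
# implementations. These are deliberately written as direct transcriptions
# of the definitions, sharing no code with the package internals.

# Greedy tag-centric pruning, re-derived from the rule definition: walk the
# variants in the given order; each still-unclustered variant opens a new
# cluster and absorbs every later unclustered variant whose r2 with it
# exceeds the cutoff.
oracle_greedy_prune <- function(m, order_ids, cutoff) {
  remaining <- order_ids
  clusters <- list()
  while (length(remaining) > 0) {
    tag <- remaining[1]
    remaining <- remaining[-1]
    in_ld <- remaining[m[tag, remaining] > cutoff]
    clusters[[length(clusters) + 1]] <- list(tag = tag,
                                             members = c(tag, in_ld))
    remaining <- setdiff(remaining, in_ld)
  }
  clusters
}

# Single-linkage clustering at the same cutoff (transitive closure), used to
# document where the greedy rule differs from it.
oracle_single_linkage <- function(m, ids, cutoff) {
  adj <- m[ids, ids, drop = FALSE] > cutoff
  diag(adj) <- TRUE
  comp <- seq_along(ids)
  repeat {
    changed <- FALSE
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  unname(split(ids, comp))
}

# Exact two-sided permutation p-value for the rank-sum comparison,
# enumerating index subsets directly.
oracle_exact_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  k <- length(a)
  r <- rank(pooled)
  mu <- k * (length(b)) / 2
  u_obs <- sum(r[seq_len(k)]) - k * (k + 1) / 2
  subsets <- utils::combn(n, k)
  us <- apply(subsets, 2, function(ix) sum(r[ix]) - k * (k + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Brute-force shared-trait edge weights: for every normalized trait, count
# the unordered gene pairs sharing it, then aggregate per pair.
oracle_network_weights <- function(records) {
  gt <- unique(data.frame(g = records$gene_symbol,
                          t = polyqprofiler::normalize_trait(records$trait_label)))
  out <- new.env(parent = emptyenv())
  for (tr in unique(gt$t)) {
    genes <- sort(gt$g[gt$t == tr])
    if (length(genes) < 2) next
    for (i in seq_len(length(genes) - 1)) for (j in seq((i + 1), length(genes))) {
      key <- paste(genes[i], genes[j], sep = "|")
      prev <- if (exists(key, envir = out)) get(key, envir = out) else 0L
      assign(key, prev + 1L, envir = out)
    }
  }
  weights <- sort(vapply(ls(out), function(k) get(k, envir = out), integer(1)))
  weights
}

# All multisets of size k over the values 0..3, as a list of sorted vectors.
score_multisets <- function(k) {
  if (k == 1) return(as.list(0:3))
  # combinations with repetition via combn over shifted indices
  idx <- utils::combn(seq_len(4 + k - 1), k)
  lapply(seq_len(ncol(idx)), function(j) idx[, j] - seq_len(k))
}

# Small random association catalog (plain construction, no package
# generators) for property tests.
random_catalog <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    gene_symbol = sample(sprintf("G%d", 1:4), n, replace = TRUE),
    gene_id = "ENSG00000000001",
    trait_label = sample(sprintf("trait %d", 1:12), n, replace = TRUE),
    trait_category = sample(c("measurement", "disease"), n, replace = TRUE),
    study_id = sprintf("S%03d", seq_len(n)),
    pubmed_id = ifelse(stats::runif(n) < 0.8, sprintf("PM%05d", seq_len(n)),
                       NA_character_),
    source = "GWAS_catalog",
    l2g = round(stats::runif(n), 3),
    variant_id = sprintf("rs%05d", sample.int(99999, n)),
    chrom = "1",
    pos = sample.int(1e6, n),
    gwas_p = 10^stats::runif(n, -20, -7.5),
    effect = stats::rnorm(n, 0, 0.05),
    effect_ci_low = NA_real_,
    effect_ci_high = NA_real_,
    effect_type = "beta",
    ancestries = "EUR"
  )
}
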