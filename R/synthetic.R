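#' @title Seeded synthetic-data generators
#' @description
#' Generators for association catalogs with controllable sharing/provenance
#' structure and for block-structured LD matrices. Both are pure functions
#' of their spec (including its seed): the global RNG state is saved and
#' restored, and the same spec always yields byte-identical output.
#' @name polyq-synthetic
NULL

with_spec_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification for a synthetic association catalog
#'
#' @param n_genes Number of genes (`G1`, `G2`, ...), >= 1.
#' @param traits_per_gene Expected number of traits per gene (Poisson mean
#'   for the gene-specific traits on top of any planted shared traits).
#' @param l2g_mix Fraction of records drawn above `l2g_cutoff`.
#' @param l2g_cutoff The cutoff the mixture refers to (default 0.5).
#' @param category_mix Named probability vector over trait categories
#'   (must sum to 1).
#' @param provenance_mix Fraction of records lacking a PubMed id (assigned
#'   to biobank-level source releases).
#' @param shared_trait_pairs List of `list(gene_a, gene_b, n_shared)`
#'   triples; each plants exactly `n_shared` traits shared by that pair and
#'   by no other gene.
#' @param seed Integer RNG seed.
#' @return A list of class `catalog_spec`.
#' @export
catalog_spec <- function(n_genes = 5,
                         traits_per_gene = 10,
                         l2g_mix = 0.5,
                         l2g_cutoff = 0.5,
                         category_mix = c(measurement = 0.6, disease = 0.4),
                         provenance_mix = 0.15,
                         shared_trait_pairs = list(),
                         seed = 1L) {
  stopifnot(n_genes >= 1, traits_per_gene >= 0,
            l2g_mix >= 0, l2g_mix <= 1,
            provenance_mix >= 0, provenance_mix <= 1,
            l2g_cutoff >= 0, l2g_cutoff <= 1)
  if (abs(sum(category_mix) - 1) > 1e-9 || any(category_mix < 0)) {
    abort("`category_mix` must be non-negative and sum to 1.",
          class = "polyq_spec_error")
  }
  structure(
    list(n_genes = as.integer(n_genes), traits_per_gene = traits_per_gene,
         l2g_mix = l2g_mix, l2g_cutoff = l2g_cutoff,
         category_mix = category_mix, provenance_mix = provenance_mix,
         shared_trait_pairs = shared_trait_pairs, seed = as.integer(seed)),
    class = "catalog_spec"
  )
}

BIOBANK_SOURCES <- c("FinnGen_R6", "UKB_NealeLab_R2", "UKB_SAIGE")

#' Generate a synthetic association catalog
#'
#' Emulates a gene-trait catalog snapshot: per gene, a planted set of
#' pair-shared traits (realized shared-trait counts equal the spec exactly,
#' and no sharing arises outside the planted pairs) plus a Poisson number
#' of gene-specific traits, each yielding one association record with a
#' synthetic study, index variant, p-value, and effect. Records lack a
#' PubMed id with probability `provenance_mix`, in which case their source
#' is a biobank-level release. Deterministic given the spec seed.
#'
#' @param spec A [catalog_spec()].
#' @return An association tibble in the [read_association_table()] schema.
#' @export
generate_catalog <- function(spec) {
  stopifnot(inherits(spec, "catalog_spec"))
  genes <- sprintf("G%d", seq_len(spec$n_genes))
  planted <- stats::setNames(vector("list", spec$n_genes), genes)
  for (p in spec$shared_trait_pairs) {
    a <- p[[1]]; b <- p[[2]]; k <- p[[3]]
    if (!(a %in% genes) || !(b %in% genes) || a == b) {
      abort(sprintf("Invalid shared pair (%s, %s).", a, b),
            class = "polyq_spec_error")
    }
    labels <- sprintf("shared trait %s %s %d", tolower(a), tolower(b), seq_len(k))
    planted[[a]] <- c(planted[[a]], labels)
    planted[[b]] <- c(planted[[b]], labels)
  }
  n_planted <- lengths(planted)
  if (any(n_planted > spec$traits_per_gene)) {
    abort("Planted shared traits exceed `traits_per_gene`.",
          class = "polyq_spec_error")
  }
  with_spec_seed(spec$seed, {
    rows <- purrr::map(seq_along(genes), function(i) {
      g <- genes[i]
      n_extra <- stats::rpois(1, spec$traits_per_gene - n_planted[i])
      traits <- c(planted[[g]],
                  if (n_extra > 0) sprintf("%s specific trait %d", tolower(g),
                                           seq_len(n_extra)))
      n <- length(traits)
      if (n == 0) return(NULL)
      above <- stats::runif(n) < spec$l2g_mix
      l2g <- ifelse(above,
                    stats::runif(n, spec$l2g_cutoff + 1e-6, 1),
                    stats::runif(n, 0, spec$l2g_cutoff))
      no_pm <- stats::runif(n) < spec$provenance_mix
      tibble(
        gene_symbol = g,
        gene_id = sprintf("ENSG%011d", i),
        trait_label = traits,
        trait_category = sample(names(spec$category_mix), n, replace = TRUE,
                                prob = spec$category_mix),
        study_id = sprintf("SIM_%s_S%03d", g, seq_len(n)),
        pubmed_id = ifelse(no_pm, NA_character_,
                           sprintf("9%06d", i * 1000 + seq_len(n))),
        source = ifelse(no_pm,
                        sample(BIOBANK_SOURCES, n, replace = TRUE),
                        "GWAS_catalog"),
        l2g = l2g,
        variant_id = sprintf("rs9%03d%04d", i, seq_len(n)),
        chrom = as.character(1 + (i - 1) %% 22),
        pos = as.integer(1e6 * i + 1000 * seq_len(n)),
        gwas_p = 10^stats::runif(n, -30, log10(5e-8)),
        effect = round(stats::rnorm(n, 0, 0.05), 4),
        effect_ci_low = NA_real_,
        effect_ci_high = NA_real_,
        effect_type = "beta",
        ancestries = "EUR"
      )
    })
    dplyr::bind_rows(rows)
  })
}

#' Specification for a block-structured LD matrix
#'
#' @param block_sizes Integer vector of haplotype block sizes.
#' @param within_r2 Central r^2 for within-block pairs.
#' @param between_r2 Central r^2 for between-block pairs
#'   (`0 <= between_r2 < within_r2 <= 1`).
#' @param r2_cutoff The pruning cutoff the blocks must straddle: jitter is
#'   clipped so within-block entries stay strictly above it and
#'   between-block entries stay at or below it, guaranteeing deterministic
#'   block recovery (`between_r2 <= r2_cutoff < within_r2`).
#' @param seed Integer RNG seed.
#' @return A list of class `ld_block_spec`.
#' @export
ld_block_spec <- function(block_sizes, within_r2 = 0.8, between_r2 = 0.1,
                          r2_cutoff = 0.5, seed = 1L) {
  stopifnot(length(block_sizes) >= 1, all(block_sizes >= 1))
  if (!(between_r2 >= 0 && between_r2 < within_r2 && within_r2 <= 1)) {
    abort("Require 0 <= between_r2 < within_r2 <= 1.", class = "polyq_spec_error")
  }
  if (!(between_r2 <= r2_cutoff && r2_cutoff < within_r2)) {
    abort("Require between_r2 <= r2_cutoff < within_r2.", class = "polyq_spec_error")
  }
  structure(
    list(block_sizes = as.integer(block_sizes), within_r2 = within_r2,
         between_r2 = between_r2, r2_cutoff = r2_cutoff,
         seed = as.integer(seed)),
    class = "ld_block_spec"
  )
}

#' Generate a block-structured LD matrix
#'
#' Within-block pairs receive `within_r2` plus uniform jitter of up to
#' 0.05, clipped to stay strictly above `r2_cutoff` (and at most 1);
#' between-block pairs receive `between_r2` plus the same jitter, clipped
#' to stay at or below `r2_cutoff` (and at least 0). Pruning the result at
#' `r2_cutoff` therefore recovers the blocks exactly, including at
#' boundary settings such as `within_r2 = 0.51` against a cutoff of 0.5.
#'
#' @param spec An [ld_block_spec()].
#' @param variant_ids Optional ids for the variants (defaults to
#'   `v01`, `v02`, ...), block by block.
#' @return An [ld_matrix()].
#' @export
generate_ld_blocks <- function(spec, variant_ids = NULL) {
  stopifnot(inherits(spec, "ld_block_spec"))
  n <- sum(spec$block_sizes)
  if (is.null(variant_ids)) variant_ids <- sprintf("v%02d", seq_len(n))
  stopifnot(length(variant_ids) == n, !anyDuplicated(variant_ids))
  block <- rep(seq_along(spec$block_sizes), spec$block_sizes)
  with_spec_seed(spec$seed, {
    m <- diag(1, n)
    dimnames(m) <- list(variant_ids, variant_ids)
    eps <- 1e-6
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        jit <- stats::runif(1, -0.05, 0.05)
        v <- if (block[i] == block[j]) {
          min(1, max(spec$r2_cutoff + eps, spec$within_r2 + jit))
        } else {
          max(0, min(spec$r2_cutoff, spec$between_r2 + jit))
        }
        m[i, j] <- v
        m[j, i] <- v
      }
    }
    ld_matrix(round(m, 6))
  })
}
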