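#' Consequence severity ranking
#'
#' Returns the shipped total order of variant consequence terms, most severe
#' first, following the conventional Ensembl VEP severity ranking (splice
#' terms above UTR terms above intronic, etc.).
#'
#' @param path Optional path to an alternative severity TSV (single column
#'   `consequence`, most severe first).
#' @return Character vector of consequence terms, most severe first.
#' @export
severity_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "consequence_severity.tsv",
                        package = "polyqprofiler", mustWork = TRUE)
  }
  terms <- readr::read_tsv(path, col_types = "c", progress = FALSE)$consequence
  if (anyDuplicated(terms)) {
    abort("Severity table contains duplicate terms.", class = "polyq_validation_error")
  }
  terms
}

#' Most severe consequence among a set of terms
#'
#' @param annotations Character vector of consequence terms.
#' @param table Severity order from [severity_table()].
#' @return The single term with the smallest (most severe) rank.
#' @examples
#' most_severe(c("intron_variant", "splice_region_variant"))
#' @export
most_severe <- function(annotations, table = severity_table()) {
  annotations <- unique(annotations)
  unknown <- setdiff(annotations, table)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown consequence term(s): %s", paste(unknown, collapse = ", ")),
          class = "polyq_validation_error")
  }
  if (length(annotations) == 0) {
    abort("No consequence terms supplied.", class = "polyq_validation_error")
  }
  table[min(match(annotations, table))]
}

#' Prune index variants into independent signals (haplotypes)
#'
#' Groups a locus's GWAS index variants into haplotypes by greedy
#' tag-centric clustering on pairwise LD: variants are processed in
#' canonical order (ascending position, ties by ascending GWAS p-value,
#' then lexicographic id); the first unassigned variant becomes a tag, and
#' every later unassigned variant with r^2(tag, v) strictly greater than
#' `r2_cutoff` joins that tag's haplotype. The position-major order mirrors
#' LD-pruning tools that retain the first variant of a position-sorted
#' input list. Tags of distinct haplotypes are pairwise not in LD
#' (r^2 <= cutoff), and membership partitions the input variants.
#'
#' Missing r^2 entries are treated as 0 (independent) with a warning.
#'
#' @param variants Tibble with columns `variant_id`, `pos`, `gwas_p` (one
#'   row per distinct variant; `gwas_p` is the best p-value observed for the
#'   variant and only breaks position ties).
#' @param ld An [ld_matrix()] covering every variant.
#' @param r2_cutoff LD pruning cutoff in `[0,1)`; membership requires
#'   r^2 strictly greater than this value.
#' @return A tibble with one row per haplotype: `haplotype_index` (assigned
#'   by ascending tag position), `tag_variant`, `member_variants`
#'   (list-column of ids in canonical order), `n_members`.
#' @export
prune_to_haplotypes <- function(variants, ld, r2_cutoff = 0.5) {
  stopifnot(is.data.frame(variants),
            all(c("variant_id", "pos", "gwas_p") %in% names(variants)),
            r2_cutoff >= 0, r2_cutoff < 1)
  variants <- as_tibble(variants)
  if (anyDuplicated(variants$variant_id)) {
    abort("Duplicate variant ids in pruning input.", class = "polyq_validation_error")
  }
  absent <- setdiff(variants$variant_id, rownames(ld))
  if (length(absent) > 0) {
    abort(sprintf("Variant(s) absent from LD matrix: %s",
                  paste(absent, collapse = ", ")),
          class = "polyq_validation_error")
  }
  ord <- order(variants$pos, variants$gwas_p, variants$variant_id)
  ids <- variants$variant_id[ord]
  pos <- variants$pos[ord]
  m <- unclass(ld)[ids, ids, drop = FALSE]
  if (anyNA(m)) {
    warn("Missing r^2 entries treated as 0 (independent).",
         class = "polyq_missing_ld_warning")
    m[is.na(m)] <- 0
  }
  assigned <- rep(FALSE, length(ids))
  tags <- integer(0)
  members <- list()
  for (i in seq_along(ids)) {
    if (assigned[i]) next
    joins <- which(!assigned & m[i, ] > r2_cutoff)
    joins <- union(i, joins)
    assigned[joins] <- TRUE
    tags <- c(tags, i)
    members <- c(members, list(ids[sort(joins)]))
  }
  hap_ord <- order(pos[tags])
  tibble(
    haplotype_index = seq_along(tags),
    tag_variant = ids[tags][hap_ord],
    member_variants = members[hap_ord],
    n_members = lengths(members)[hap_ord]
  )
}

#' Identify independent signals per gene
#'
#' Runs [prune_to_haplotypes()] once per gene over the distinct index
#' variants of an association catalog, then attaches each association record
#' to its variant's haplotype via [assign_traits()].
#'
#' @param records Association catalog tibble (already prioritized/filtered).
#' @param ld_by_gene Named list of [ld_matrix()] objects, one per gene
#'   symbol present in `records`.
#' @param r2_cutoff LD pruning cutoff.
#' @return A tibble of haplotypes across genes with columns `gene_symbol`,
#'   `haplotype_index`, `tag_variant`, `member_variants`, `n_members`,
#'   `assigned_traits` (list-column of tibbles), `n_traits`.
#' @export
identify_signals <- function(records, ld_by_gene, r2_cutoff = 0.5) {
  genes <- unique(records$gene_symbol)
  missing_ld <- setdiff(genes, names(ld_by_gene))
  if (length(missing_ld) > 0) {
    abort(sprintf("No LD matrix supplied for gene(s): %s",
                  paste(missing_ld, collapse = ", ")),
          class = "polyq_validation_error")
  }
  haps <- purrr::map(genes, function(g) {
    rg <- records[records$gene_symbol == g, ]
    vars <- rg |>
      dplyr::group_by(.data$variant_id) |>
      dplyr::summarise(pos = .data$pos[1], gwas_p = min(.data$gwas_p),
                       .groups = "drop")
    h <- prune_to_haplotypes(vars, ld_by_gene[[g]], r2_cutoff)
    h$gene_symbol <- g
    h
  })
  haps <- dplyr::bind_rows(haps)[, c("gene_symbol", "haplotype_index",
                                     "tag_variant", "member_variants",
                                     "n_members")]
  assign_traits(records, haps)
}

#' Assign trait associations to haplotypes
#'
#' Attaches every association record to the haplotype (of its gene) that
#' contains its index variant. A record whose variant belongs to no
#' haplotype of its gene is an error.
#'
#' @param records Association catalog tibble.
#' @param haplotypes Haplotype tibble with `gene_symbol`, `haplotype_index`,
#'   `tag_variant`, `member_variants`.
#' @return `haplotypes` with added list-column `assigned_traits` (tibbles of
#'   `trait_label`, `study_id`, `l2g`, `variant_id`) and `n_traits`.
#' @export
assign_traits <- function(records, haplotypes) {
  key <- function(g, i) paste(g, i, sep = "\r")
  lookup <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(haplotypes))) {
    for (v in haplotypes$member_variants[[r]]) {
      assign(key(haplotypes$gene_symbol[r], v), r, envir = lookup)
    }
  }
  row_of <- vapply(seq_len(nrow(records)), function(i) {
    k <- key(records$gene_symbol[i], records$variant_id[i])
    if (!exists(k, envir = lookup)) {
      abort(sprintf("Variant %s of gene %s belongs to no haplotype.",
                    records$variant_id[i], records$gene_symbol[i]),
            class = "polyq_validation_error")
    }
    get(k, envir = lookup)
  }, integer(1))
  haplotypes$assigned_traits <- purrr::map(seq_len(nrow(haplotypes)), function(r) {
    sub <- records[row_of == r, c("trait_label", "study_id", "l2g", "variant_id")]
    sub[order(sub$trait_label, sub$study_id), ]
  })
  haplotypes$n_traits <- vapply(haplotypes$assigned_traits, nrow, integer(1))
  haplotypes
}

#' Flatten a haplotype table for TSV export
#'
#' @param haplotypes Haplotype tibble from [identify_signals()].
#' @return A plain tibble with `member_variants` semicolon-joined and trait
#'   counts, suitable for [readr::write_tsv()].
#' @export
flatten_haplotypes <- function(haplotypes) {
  tibble(
    gene_symbol = haplotypes$gene_symbol,
    haplotype_index = haplotypes$haplotype_index,
    tag_variant = haplotypes$tag_variant,
    member_variants = vapply(haplotypes$member_variants,
                             paste, character(1), collapse = ";"),
    n_members = lengths(haplotypes$member_variants),
    n_traits = if ("n_traits" %in% names(haplotypes)) haplotypes$n_traits
               else NA_integer_
  )
}
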