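#' @title Table IO for catalog snapshots
#' @description
#' All pipeline inputs are UTF-8 tab-separated tables with a header row and
#' "." for missing values, mirroring the database snapshots they emulate:
#' a gene-trait association catalog, per-variant annotations, long-format
#' pairwise LD, per-gene feature tables, and OMIM-style phenotype entries.
#' Readers parse every row or reject it with row-numbered diagnostics;
#' writers round-trip all fields exactly.
#' @name polyq-io
NULL

ASSOCIATION_COLUMNS <- c(
  "gene_symbol", "gene_id", "trait_label", "trait_category", "study_id",
  "pubmed_id", "source", "l2g", "variant_id", "chrom", "pos", "gwas_p",
  "effect", "effect_ci_low", "effect_ci_high", "effect_type", "ancestries"
)

ANNOTATION_COLUMNS <- c(
  "variant_id", "consequence", "cadd", "effect_allele", "eur_af",
  "splice_flag", "eqtl_gene_ids"
)

FEATURE_COLUMNS <- c(
  "gene_symbol", "pli", "oe_lof", "tissue_class", "druggable_any"
)

OMIM_COLUMNS <- c(
  "gene_symbol", "phenotype_label", "mim_number", "inheritance",
  "susceptibility_flag", "cag_related_flag"
)

HPA_TISSUE_CLASSES <- c(
  "tissue_enriched", "group_enriched", "tissue_enhanced",
  "low_tissue_specificity", "not_detected"
)

read_raw_tsv <- function(path, required, what) {
  if (!file.exists(path)) {
    abort(sprintf("%s table not found: %s", what, path), class = "polyq_io_error")
  }
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       na = ".", progress = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort(sprintf("%s table %s is missing required column(s): %s",
                  what, path, paste(missing, collapse = ", ")),
          class = "polyq_schema_error")
  }
  x
}

num_col <- function(x, col, what, rows_msgs) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(v))
  if (length(bad) > 0) {
    rows_msgs$push(sprintf("column '%s': non-numeric value at row(s) %s",
                           col, paste(bad, collapse = ", ")))
  }
  v
}

# tiny mutable accumulator for row-level diagnostics
msg_stack <- function() {
  msgs <- character()
  list(
    push = function(m) msgs <<- c(msgs, m),
    get = function() msgs
  )
}

check_domain <- function(v, ok, col, rows_msgs) {
  bad <- which(!is.na(v) & !ok(v))
  if (length(bad) > 0) {
    rows_msgs$push(sprintf("column '%s': value out of domain at row(s) %s",
                           col, paste(bad, collapse = ", ")))
  }
}

#' Read a gene-trait association catalog
#'
#' Parses a TSV snapshot of GWAS gene-trait association signals: one row per
#' signal with gene identity, trait label/category, study provenance
#' (study id, PubMed id, source release), L2G score, index variant
#' (rsID, chromosome, 1-based GRCh38 position), GWAS p-value, effect
#' estimate with CI and type, and the study's ancestry labels
#' (semicolon-joined). A record counts as peer-reviewed iff `pubmed_id` is
#' non-missing.
#'
#' @param path Path to a TSV file with "." for missing values.
#' @param config Optional [threshold_config()] (currently used for schema
#'   conventions only).
#' @return A tibble with one row per association record.
#' @export
read_association_table <- function(path, config = threshold_config()) {
  x <- read_raw_tsv(path, ASSOCIATION_COLUMNS, "association")
  msgs <- msg_stack()
  out <- tibble(
    gene_symbol = x$gene_symbol,
    gene_id = x$gene_id,
    trait_label = x$trait_label,
    trait_category = x$trait_category,
    study_id = x$study_id,
    pubmed_id = x$pubmed_id,
    source = x$source,
    l2g = num_col(x$l2g, "l2g", "association", msgs),
    variant_id = x$variant_id,
    chrom = x$chrom,
    pos = as.integer(num_col(x$pos, "pos", "association", msgs)),
    gwas_p = num_col(x$gwas_p, "gwas_p", "association", msgs),
    effect = num_col(x$effect, "effect", "association", msgs),
    effect_ci_low = num_col(x$effect_ci_low, "effect_ci_low", "association", msgs),
    effect_ci_high = num_col(x$effect_ci_high, "effect_ci_high", "association", msgs),
    effect_type = x$effect_type,
    ancestries = x$ancestries
  )
  check_domain(out$l2g, function(v) v >= 0 & v <= 1, "l2g", msgs)
  check_domain(out$pos, function(v) v >= 1, "pos", msgs)
  check_domain(out$gwas_p, function(v) v > 0 & v <= 1, "gwas_p", msgs)
  bad_or <- which(!is.na(out$effect_type) & out$effect_type == "odds_ratio" &
                    !is.na(out$effect) & out$effect <= 0)
  if (length(bad_or) > 0) {
    msgs$push(sprintf("column 'effect': non-positive odds ratio at row(s) %s",
                      paste(bad_or, collapse = ", ")))
  }
  if (length(msgs$get()) > 0) {
    abort(paste0("Invalid association table ", path, ":\n  ",
                 paste(msgs$get(), collapse = "\n  ")),
          class = "polyq_validation_error")
  }
  out
}

#' Write a gene-trait association catalog
#'
#' @param records Association tibble (as returned by
#'   [read_association_table()]).
#' @param path Output TSV path; missing values are written as ".".
#' @return `path`, invisibly.
#' @export
write_association_table <- function(records, path) {
  readr::write_tsv(records[, ASSOCIATION_COLUMNS], path, na = ".", progress = FALSE)
  invisible(path)
}

#' Read a per-variant annotation table
#'
#' One row per index variant: most-severe consequence term (drawn from the
#' shipped severity vocabulary, see [severity_table()]), CADD score, effect
#' allele, European-reference effect-allele frequency, a splice-alteration
#' flag, and any eQTL target gene ids (semicolon-joined).
#'
#' @param path TSV path.
#' @return A tibble with one row per variant.
#' @export
read_annotation_table <- function(path) {
  x <- read_raw_tsv(path, ANNOTATION_COLUMNS, "annotation")
  msgs <- msg_stack()
  out <- tibble(
    variant_id = x$variant_id,
    consequence = x$consequence,
    cadd = num_col(x$cadd, "cadd", "annotation", msgs),
    effect_allele = x$effect_allele,
    eur_af = num_col(x$eur_af, "eur_af", "annotation", msgs),
    splice_flag = as.logical(x$splice_flag),
    eqtl_gene_ids = x$eqtl_gene_ids
  )
  check_domain(out$eur_af, function(v) v >= 0 & v <= 1, "eur_af", msgs)
  check_domain(out$cadd, function(v) v >= 0, "cadd", msgs)
  vocab <- severity_table()
  bad <- which(!is.na(out$consequence) & !(out$consequence %in% vocab))
  if (length(bad) > 0) {
    msgs$push(sprintf("column 'consequence': term outside severity vocabulary at row(s) %s",
                      paste(bad, collapse = ", ")))
  }
  if (length(msgs$get()) > 0) {
    abort(paste0("Invalid annotation table ", path, ":\n  ",
                 paste(msgs$get(), collapse = "\n  ")),
          class = "polyq_validation_error")
  }
  out
}

#' @rdname read_annotation_table
#' @param annotations Annotation tibble.
#' @export
write_annotation_table <- function(annotations, path) {
  readr::write_tsv(annotations[, ANNOTATION_COLUMNS], path, na = ".", progress = FALSE)
  invisible(path)
}

#' Construct a validated LD matrix
#'
#' @param r2 Square numeric matrix of pairwise r^2 with variant ids as
#'   dimnames. `NA` entries mark unobserved pairs; the diagonal must be 1 and
#'   the matrix symmetric with entries in `[0,1]`.
#' @return An object of class `ld_matrix`.
#' @export
ld_matrix <- function(r2) {
  stopifnot(is.matrix(r2), nrow(r2) == ncol(r2))
  ids <- rownames(r2)
  if (is.null(ids) || is.null(colnames(r2)) || !identical(ids, colnames(r2))) {
    abort("LD matrix must carry identical row/column variant ids.",
          class = "polyq_validation_error")
  }
  if (anyDuplicated(ids)) {
    abort("Duplicate variant ids in LD matrix.", class = "polyq_validation_error")
  }
  if (any(abs(diag(r2) - 1) > 1e-9, na.rm = TRUE) || anyNA(diag(r2))) {
    abort("LD matrix diagonal must be exactly 1.", class = "polyq_validation_error")
  }
  both <- !is.na(r2) & !is.na(t(r2))
  if (any(abs(r2[both] - t(r2)[both]) > 1e-9)) {
    abort("LD matrix is not symmetric.", class = "polyq_validation_error")
  }
  if (any(r2 < 0 | r2 > 1, na.rm = TRUE)) {
    abort("LD r^2 entries must lie in [0,1].", class = "polyq_validation_error")
  }
  # propagate one-sided observations symmetrically
  miss <- is.na(r2) & !is.na(t(r2))
  r2[miss] <- t(r2)[miss]
  structure(r2, class = c("ld_matrix", "matrix", "array"))
}

#' Read a pairwise LD matrix
#'
#' Accepts either a long-format TSV (`id_a`, `id_b`, `r2`) or a square
#' matrix TSV whose first column holds variant ids. Unobserved pairs are
#' kept as missing; conflicting duplicate pairs (|r2_ab - r2_ba| > 1e-9)
#' raise a consistency error.
#'
#' @param path TSV path.
#' @return An [ld_matrix()] object.
#' @export
read_ld_matrix <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       na = ".", progress = FALSE)
  if (all(c("id_a", "id_b", "r2") %in% names(x))) {
    ids <- sort(unique(c(x$id_a, x$id_b)))
    m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
    diag(m) <- 1
    r2 <- suppressWarnings(as.numeric(x$r2))
    bad <- which(!is.na(x$r2) & is.na(r2))
    if (length(bad) > 0) {
      abort(sprintf("Non-numeric r2 at row(s) %s of %s",
                    paste(bad, collapse = ", "), path),
            class = "polyq_validation_error")
    }
    for (i in seq_len(nrow(x))) {
      a <- x$id_a[i]; b <- x$id_b[i]; v <- r2[i]
      if (a == b) next
      prev <- m[a, b]
      if (!is.na(prev) && !is.na(v) && abs(prev - v) > 1e-9) {
        abort(sprintf("Conflicting r2 for pair (%s, %s) in %s: %g vs %g",
                      a, b, path, prev, v),
              class = "polyq_consistency_error")
      }
      m[a, b] <- v
      m[b, a] <- v
    }
    return(ld_matrix(m))
  }
  # square layout: first column = variant ids
  ids <- x[[1]]
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  ld_matrix(m)
}

#' Write an LD matrix as a long-format TSV
#'
#' Emits one row per unordered observed pair (upper triangle), columns
#' `id_a`, `id_b`, `r2`.
#'
#' @param ld An [ld_matrix()] object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  ids <- rownames(ld)
  idx <- which(upper.tri(ld), arr.ind = TRUE)
  out <- tibble(
    id_a = ids[idx[, 1]],
    id_b = ids[idx[, 2]],
    r2 = ld[idx]
  )
  readr::write_tsv(out[!is.na(out$r2), ], path, na = ".", progress = FALSE)
  invisible(path)
}

#' Read per-gene feature and interaction tables
#'
#' The feature table carries one row per gene: gnomAD constraint (pLI and
#' observed/expected LoF ratio), Human Protein Atlas tissue-specificity
#' class, and a druggable-any indicator. The companion interaction table
#' carries one row per (gene, partner) molecular interaction with its MI
#' confidence score. Together they form a gene feature profile set.
#'
#' @param features_path TSV with columns `gene_symbol`, `pli`, `oe_lof`,
#'   `tissue_class`, `druggable_any`.
#' @param interactions_path TSV with columns `gene_symbol`, `partner`,
#'   `mi_score`; may be absent (`NULL`) for genes with no interaction data.
#' @return A list of class `gene_features` with elements `genes` and
#'   `interactions` (tibbles).
#' @export
read_gene_features <- function(features_path, interactions_path = NULL) {
  x <- read_raw_tsv(features_path, FEATURE_COLUMNS, "gene feature")
  msgs <- msg_stack()
  genes <- tibble(
    gene_symbol = x$gene_symbol,
    pli = num_col(x$pli, "pli", "feature", msgs),
    oe_lof = num_col(x$oe_lof, "oe_lof", "feature", msgs),
    tissue_class = x$tissue_class,
    druggable_any = as.logical(x$druggable_any)
  )
  check_domain(genes$pli, function(v) v >= 0 & v <= 1, "pli", msgs)
  check_domain(genes$oe_lof, function(v) v >= 0, "oe_lof", msgs)
  bad <- which(!is.na(genes$tissue_class) & !(genes$tissue_class %in% HPA_TISSUE_CLASSES))
  if (length(bad) > 0) {
    msgs$push(sprintf("column 'tissue_class': unknown class at row(s) %s",
                      paste(bad, collapse = ", ")))
  }
  interactions <- tibble(gene_symbol = character(), partner = character(),
                         mi_score = double())
  if (!is.null(interactions_path)) {
    y <- read_raw_tsv(interactions_path, c("gene_symbol", "partner", "mi_score"),
                      "interaction")
    interactions <- tibble(
      gene_symbol = y$gene_symbol,
      partner = y$partner,
      mi_score = num_col(y$mi_score, "mi_score", "interaction", msgs)
    )
    check_domain(interactions$mi_score, function(v) v >= 0 & v <= 1, "mi_score", msgs)
  }
  if (length(msgs$get()) > 0) {
    abort(paste0("Invalid gene feature tables:\n  ",
                 paste(msgs$get(), collapse = "\n  ")),
          class = "polyq_validation_error")
  }
  gene_features(genes, interactions)
}

#' Construct a gene feature profile set
#'
#' @param genes Tibble of per-gene features (see [read_gene_features()]).
#' @param interactions Tibble of (gene_symbol, partner, mi_score) rows.
#' @return A list of class `gene_features`.
#' @export
gene_features <- function(genes, interactions = NULL) {
  genes <- as_tibble(genes)
  if (anyDuplicated(genes$gene_symbol)) {
    dup <- unique(genes$gene_symbol[duplicated(genes$gene_symbol)])
    abort(sprintf("Duplicate gene_symbol in feature table: %s",
                  paste(dup, collapse = ", ")),
          class = "polyq_validation_error")
  }
  if (is.null(interactions)) {
    interactions <- tibble(gene_symbol = character(), partner = character(),
                           mi_score = double())
  }
  structure(list(genes = genes, interactions = as_tibble(interactions)),
            class = "gene_features")
}

#' @export
print.gene_features <- function(x, ...) {
  cat(sprintf("<gene_features> %d genes, %d interaction records\n",
              nrow(x$genes), nrow(x$interactions)))
  invisible(x)
}

#' Report missing features per gene
#'
#' Lists, per feature category (constraint, expression, interactions,
#' druggability), the genes whose value is missing. Duplicate gene symbols
#' are rejected.
#'
#' @param profiles A `gene_features` object.
#' @return A tibble with columns `category` and `gene_symbol`, one row per
#'   missing feature; zero rows when every profile is complete.
#' @export
validate_profile_table <- function(profiles) {
  stopifnot(inherits(profiles, "gene_features"))
  g <- profiles$genes
  with_ix <- unique(profiles$interactions$gene_symbol)
  miss <- list(
    constraint = g$gene_symbol[is.na(g$pli)],
    expression = g$gene_symbol[is.na(g$tissue_class)],
    interactions = setdiff(g$gene_symbol, with_ix),
    druggability = g$gene_symbol[is.na(g$druggable_any)]
  )
  out <- purrr::imap(miss, function(genes, cat) {
    tibble(category = rep(cat, length(genes)), gene_symbol = genes)
  })
  dplyr::bind_rows(out)
}

#' Read an OMIM-style phenotype entry table
#'
#' One row per (gene, phenotype) entry with MIM number, inheritance mode, a
#' susceptibility flag (true iff the phenotype label carries a
#' "susceptibility to" designation) and a flag for CAG repeat-length-related
#' entries.
#'
#' @param path TSV path.
#' @return A tibble of OMIM entries.
#' @export
read_omim_table <- function(path) {
  x <- read_raw_tsv(path, OMIM_COLUMNS, "OMIM")
  out <- tibble(
    gene_symbol = x$gene_symbol,
    phenotype_label = x$phenotype_label,
    mim_number = x$mim_number,
    inheritance = x$inheritance,
    susceptibility_flag = as.logical(x$susceptibility_flag),
    cag_related_flag = as.logical(x$cag_related_flag)
  )
  label_says <- startsWith(normalize_trait(out$phenotype_label), "susceptibility to")
  bad <- which(out$susceptibility_flag != label_says)
  if (length(bad) > 0) {
    abort(sprintf("OMIM susceptibility flag inconsistent with label at row(s) %s of %s",
                  paste(bad, collapse = ", "), path),
          class = "polyq_validation_error")
  }
  out
}

#' @rdname read_omim_table
#' @param entries OMIM entry tibble.
#' @export
write_omim_table <- function(entries, path) {
  readr::write_tsv(entries[, OMIM_COLUMNS], path, na = ".", progress = FALSE)
  invisible(path)
}
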