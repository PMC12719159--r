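#' Flag count-based traits
#'
#' Partitions a catalog by whether the normalized trait label matches any of
#' the supplied regular expressions (case-insensitive). The default pattern
#' list (see [default_count_trait_patterns()]) targets count-based traits
#' such as blood cell counts, which produce numerous non-specific signals
#' genome-wide. `kept` and `removed` together reproduce the input exactly,
#' in order.
#'
#' @param records Association catalog tibble.
#' @param patterns Character vector of regular expressions; an empty vector
#'   removes nothing.
#' @return A list with tibbles `kept` and `removed`.
#' @export
flag_count_traits <- function(records, patterns = default_count_trait_patterns()) {
  for (p in patterns) {
    ok <- tryCatch({ grepl(p, "x"); TRUE }, error = function(e) FALSE,
                   warning = function(w) FALSE)
    if (!ok) abort(sprintf("Invalid count-trait regex: '%s'", p),
                   class = "polyq_config_error")
  }
  norm <- normalize_trait(records$trait_label)
  hit <- rep(FALSE, nrow(records))
  for (p in patterns) hit <- hit | grepl(p, norm, ignore.case = TRUE)
  list(kept = records[!hit, , drop = FALSE],
       removed = records[hit, , drop = FALSE])
}

#' Restrict a catalog to peer-reviewed studies
#'
#' A record is peer-reviewed iff its `pubmed_id` is non-missing; records
#' without one (biobank-level releases such as FinnGen or UK Biobank rounds)
#' are removed. The report tallies the removed records by source release.
#'
#' @param records Association catalog tibble.
#' @return A list with `kept`, `removed`, and `report` (a list with
#'   `n_in`, `n_removed_non_pubmed`, `removed_by_source`, `n_retained`,
#'   `pct_removed` rounded half-up to 1 decimal).
#' @export
filter_peer_reviewed <- function(records) {
  miss <- is.na(records$pubmed_id)
  removed <- records[miss, , drop = FALSE]
  kept <- records[!miss, , drop = FALSE]
  tab <- table(removed$source)
  list(
    kept = kept,
    removed = removed,
    report = list(
      n_in = nrow(records),
      n_removed_non_pubmed = nrow(removed),
      removed_by_source = setNames(as.integer(tab), names(tab)),
      n_retained = nrow(kept),
      pct_removed = if (nrow(records) > 0)
        round_half_up(100 * nrow(removed) / nrow(records), 1) else NA_real_
    )
  )
}

#' Deduplicate traits per gene
#'
#' Keeps one record per (gene, normalized trait label): the record with the
#' highest L2G score, ties broken by lower GWAS p-value, then lexicographic
#' variant id. The output is sorted canonically (gene, normalized trait) and
#' is therefore invariant to input row order.
#'
#' @param records Association catalog tibble.
#' @return The deduplicated records.
#' @export
dedup_traits <- function(records) {
  if (nrow(records) == 0) return(records)
  norm <- normalize_trait(records$trait_label)
  ord <- order(records$gene_symbol, norm, -records$l2g, records$gwas_p,
               records$variant_id)
  x <- records[ord, , drop = FALSE]
  keep <- !duplicated(data.frame(g = x$gene_symbol,
                                 t = normalize_trait(x$trait_label)))
  x[keep, , drop = FALSE]
}

#' Run the full trait prioritization
#'
#' Composes count-trait removal, the peer-review provenance filter, and
#' per-gene trait deduplication, and reports the bookkeeping: input size,
#' removals by step and by source, retained records, unique gene-trait
#' associations after deduplication, and retained genes. Removals satisfy
#' `n_in = n_retained + n_removed_count_traits + n_removed_non_pubmed`.
#'
#' @param records Association catalog tibble (typically pre-filtered with
#'   [filter_by_l2g()]).
#' @param config A [threshold_config()] supplying the count-trait patterns.
#' @return A list with `kept` (retained, pre-dedup), `deduped`,
#'   `removed_count_traits`, `removed_non_pubmed`, and `report`.
#' @export
prioritize_catalog <- function(records, config = threshold_config()) {
  step1 <- flag_count_traits(records, config$count_trait_patterns)
  step2 <- filter_peer_reviewed(step1$kept)
  deduped <- dedup_traits(step2$kept)
  report <- list(
    n_in = nrow(records),
    n_removed_count_traits = nrow(step1$removed),
    n_removed_non_pubmed = nrow(step2$removed),
    removed_by_source = step2$report$removed_by_source,
    n_retained = nrow(step2$kept),
    n_unique_after_dedup = nrow(deduped),
    genes_retained = sort(unique(step2$kept$gene_symbol))
  )
  stopifnot(report$n_in ==
              report$n_retained + report$n_removed_count_traits +
              report$n_removed_non_pubmed)
  list(
    kept = step2$kept,
    deduped = deduped,
    removed_count_traits = step1$removed,
    removed_non_pubmed = step2$removed,
    report = report
  )
}

#' Summarize GWAS ancestry representation per study
#'
#' Counts are per study (keyed on `study_id`), not per record: a study
#' listed by several records counts once. A study is exclusive for an
#' ancestry iff its ancestry set is that singleton; "any" counts studies
#' whose set contains the ancestry. Studies with no ancestry annotation are
#' excluded from the denominator and counted separately. Percentages are
#' recomputed from the integer counts and rounded half-up to one decimal.
#'
#' @param records Tibble with at least `study_id` and `ancestries`
#'   (semicolon-joined labels, `NA` for unannotated studies).
#' @return A list of class `ancestry_summary` with `n_studies`,
#'   `n_no_ancestry`, `n_exclusive`, `n_any`, `pct_exclusive`, `pct_any`.
#' @export
summarize_ancestry <- function(records) {
  studies <- unique(records[, c("study_id", "ancestries")])
  if (anyDuplicated(studies$study_id)) {
    dup <- unique(studies$study_id[duplicated(studies$study_id)])
    abort(sprintf("Conflicting ancestry sets for study/studies: %s",
                  paste(dup, collapse = ", ")),
          class = "polyq_consistency_error")
  }
  has <- !is.na(studies$ancestries) & nzchar(studies$ancestries)
  sets <- lapply(studies$ancestries[has],
                 function(a) sort(unique(strsplit(a, ";", fixed = TRUE)[[1]])))
  n_studies <- sum(has)
  labels <- sort(unique(unlist(sets)))
  n_any <- vapply(labels, function(l) sum(vapply(sets, function(s) l %in% s,
                                                 logical(1))), integer(1))
  n_exclusive <- vapply(labels, function(l)
    sum(vapply(sets, function(s) identical(s, l), logical(1))), integer(1))
  pct <- function(n) if (n_studies > 0) round_half_up(100 * n / n_studies, 1)
    else setNames(numeric(0), character(0))
  structure(
    list(
      n_studies = n_studies,
      n_no_ancestry = sum(!has),
      n_exclusive = n_exclusive,
      n_any = n_any,
      pct_exclusive = pct(n_exclusive),
      pct_any = pct(n_any)
    ),
    class = "ancestry_summary"
  )
}

#' @export
print.ancestry_summary <- function(x, ...) {
  cat(sprintf("<ancestry_summary> %d studies with ancestry data (%d without)\n",
              x$n_studies, x$n_no_ancestry))
  for (l in names(x$n_any)) {
    cat(sprintf("  %s: exclusive %d (%.1f%%), any %d (%.1f%%)\n",
                l, x$n_exclusive[[l]], x$pct_exclusive[[l]],
                x$n_any[[l]], x$pct_any[[l]]))
  }
  invisible(x)
}

#' Classify OMIM-style phenotype entries
#'
#' Partitions entries into Mendelian disorders versus disease-susceptibility
#' entries via the susceptibility flag, and separately tallies entries
#' related to CAG repeat length.
#'
#' @param entries OMIM entry tibble (see [read_omim_table()]).
#' @return A list with integer counts `mendelian`, `susceptibility`,
#'   `cag_related`, and `n_entries`.
#' @export
classify_omim_entries <- function(entries) {
  list(
    mendelian = sum(!entries$susceptibility_flag),
    susceptibility = sum(entries$susceptibility_flag),
    cag_related = sum(entries$cag_related_flag),
    n_entries = nrow(entries)
  )
}
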