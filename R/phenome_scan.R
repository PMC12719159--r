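#' Filter a catalog by locus-to-gene score
#'
#' Keeps association records with L2G score strictly greater than the
#' cutoff (records exactly at the cutoff are dropped); input order is
#' preserved. Filtering is idempotent and commutes with catalog
#' concatenation.
#'
#' @param records Association catalog tibble.
#' @param cutoff L2G cutoff in `[0,1]`.
#' @return The retained records.
#' @export
filter_by_l2g <- function(records, cutoff = 0.5) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1, cutoff >= 0, cutoff <= 1)
  records[!is.na(records$l2g) & records$l2g > cutoff, , drop = FALSE]
}

#' Summarize a phenome scan
#'
#' Counts association signals, unique traits (on normalized labels, see
#' [normalize_trait()]), distinct gene-trait pairs, retained genes, and
#' per-category signal counts (which sum to the signal count).
#'
#' @param records Association catalog tibble.
#' @return A list of class `scan_summary`.
#' @export
summarize_scan <- function(records) {
  norm <- normalize_trait(records$trait_label)
  cats <- table(records$trait_category)
  structure(
    list(
      n_signals = nrow(records),
      n_unique_traits = length(unique(norm)),
      n_gene_trait_pairs_retained =
        nrow(unique(data.frame(g = records$gene_symbol, t = norm))),
      genes_retained = sort(unique(records$gene_symbol)),
      per_category_counts =
        setNames(as.integer(cats), names(cats))
    ),
    class = "scan_summary"
  )
}

#' @export
print.scan_summary <- function(x, ...) {
  cat(sprintf("<scan_summary> %d signals | %d unique traits | %d gene-trait pairs | %d genes\n",
              x$n_signals, x$n_unique_traits, x$n_gene_trait_pairs_retained,
              length(x$genes_retained)))
  invisible(x)
}

#' L2G threshold robustness sweep
#'
#' Counts retained records at each cutoff of a strictly increasing grid.
#' Each count equals `nrow(filter_by_l2g(records, cutoff))`, so counts are
#' weakly decreasing along the grid.
#'
#' @param records Association catalog tibble.
#' @param grid Strictly increasing numeric vector of cutoffs.
#' @return A tibble with columns `cutoff` and `n_retained`.
#' @export
threshold_sweep <- function(records, grid = seq(0, 1, by = 0.1)) {
  if (length(grid) > 1 && any(diff(grid) <= 0)) {
    abort("Sweep grid must be strictly increasing.", class = "polyq_config_error")
  }
  tibble(
    cutoff = as.numeric(grid),
    n_retained = vapply(grid, function(cc) nrow(filter_by_l2g(records, cc)),
                        integer(1))
  )
}
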