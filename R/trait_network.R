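#' Build the weighted gene-gene network of shared trait associations
#'
#' Each node is a gene weighted by its number of distinct normalized traits;
#' an undirected edge joins two genes iff they share at least one normalized
#' trait, weighted by the number of distinct shared traits. Duplicate
#' records and record order do not affect the result (set semantics), and
#' correlated-but-distinct trait labels count separately.
#'
#' @param records Association catalog tibble, pre-filtered to the intended
#'   L2G cutoff.
#' @return A list of class `trait_network` with tibbles `nodes`
#'   (`gene_symbol`, `n_traits`) and `edges` (`gene_a`, `gene_b`
#'   lexicographically ordered within a pair, `weight`, `shared_traits`
#'   list-column of normalized labels).
#' @export
build_network <- function(records) {
  gt <- unique(tibble(
    gene_symbol = records$gene_symbol,
    trait = normalize_trait(records$trait_label)
  ))
  genes <- sort(unique(gt$gene_symbol))
  nodes <- gt |>
    dplyr::count(.data$gene_symbol, name = "n_traits") |>
    dplyr::arrange(.data$gene_symbol)
  traits_of <- split(gt$trait, gt$gene_symbol)
  edges <- tibble(gene_a = character(), gene_b = character(),
                  weight = integer(), shared_traits = list())
  if (length(genes) > 1) {
    pairs <- utils::combn(genes, 2)
    rows <- purrr::map(seq_len(ncol(pairs)), function(k) {
      a <- pairs[1, k]; b <- pairs[2, k]
      shared <- sort(intersect(traits_of[[a]], traits_of[[b]]))
      if (length(shared) == 0) return(NULL)
      tibble(gene_a = a, gene_b = b, weight = length(shared),
             shared_traits = list(shared))
    })
    rows <- purrr::compact(rows)
    if (length(rows) > 0) edges <- dplyr::bind_rows(rows)
  }
  structure(list(nodes = nodes, edges = edges), class = "trait_network")
}

#' @export
print.trait_network <- function(x, ...) {
  cat(sprintf("<trait_network> %d genes, %d edges, total shared-trait weight %d\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$weight)))
  invisible(x)
}

#' Genes sharing no traits with any other gene
#'
#' @param network A [build_network()] result.
#' @param all_genes Character vector of genes to assess; genes absent from
#'   the network (no associations at all) are reported as isolated.
#' @return Sorted character vector of isolated genes.
#' @export
isolated_genes <- function(network, all_genes) {
  connected <- unique(c(network$edges$gene_a, network$edges$gene_b))
  sort(setdiff(all_genes, connected))
}

#' Export a trait network
#'
#' `edge_list_tsv` writes one row per edge with columns `gene_a`, `gene_b`,
#' `weight`, `shared_traits` (semicolon-joined); `graphml` writes a GraphML
#' file (via igraph) carrying the same node/edge attributes.
#'
#' @param network A [build_network()] result.
#' @param path Output file path.
#' @param format One of `"edge_list_tsv"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("edge_list_tsv", "graphml")) {
  format <- rlang::arg_match(format)
  if (format == "edge_list_tsv") {
    out <- tibble(
      gene_a = network$edges$gene_a,
      gene_b = network$edges$gene_b,
      weight = network$edges$weight,
      shared_traits = vapply(network$edges$shared_traits, paste,
                             character(1), collapse = ";")
    )
    readr::write_tsv(out, path, na = ".", progress = FALSE)
    return(invisible(path))
  }
  g <- igraph::graph_from_data_frame(
    d = data.frame(
      from = network$edges$gene_a,
      to = network$edges$gene_b,
      weight = network$edges$weight,
      shared_traits = vapply(network$edges$shared_traits, paste,
                             character(1), collapse = ";")
    ),
    directed = FALSE,
    vertices = data.frame(name = network$nodes$gene_symbol,
                          n_traits = network$nodes$n_traits)
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read back an exported edge list
#'
#' @param path Edge-list TSV written by [export_network()].
#' @return A tibble with `gene_a`, `gene_b`, `weight`, `shared_traits`
#'   (list-column).
#' @export
read_network_edges <- function(path) {
  x <- readr::read_tsv(path, col_types = "ccic", na = ".", progress = FALSE)
  x$shared_traits <- lapply(x$shared_traits, function(s)
    if (is.na(s)) character(0) else strsplit(s, ";", fixed = TRUE)[[1]])
  x
}
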