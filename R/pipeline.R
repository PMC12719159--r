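#' Run the full characterization pipeline over files
#'
#' Composes the five analysis stages in order -- phenome scan (L2G filter,
#' summary, threshold sweep), trait prioritization (count traits, peer
#' review, deduplication, ancestry), independent-signal identification (LD
#' pruning and trait assignment), shared-trait network, and drug-target
#' risk profiling -- reading TSV inputs and writing TSV/JSON outputs plus a
#' run manifest. Outputs are deterministic given inputs, configuration and
#' seed; timestamps appear only in the manifest so all data artifacts are
#' byte-reproducible. Each stage is identical to calling its exported
#' function directly on the intermediate files.
#'
#' @param inputs Named list of input paths: `catalog` (association TSV,
#'   required); optional `ld` (named list of long-format LD TSV paths keyed
#'   by gene symbol), `features` and `interactions` (gene feature TSVs),
#'   `omim` (OMIM entry TSV).
#' @param outdir Output directory (created if needed).
#' @param config A [threshold_config()].
#' @return Invisibly, the run manifest (a list), also written to
#'   `manifest.json` in `outdir`.
#' @export
run_pipeline <- function(inputs, outdir, config = threshold_config()) {
  stopifnot(is.list(inputs), !is.null(inputs$catalog))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  input_files <- c(catalog = inputs$catalog,
                   unlist(inputs$ld %||% list()),
                   features = inputs$features %||% NULL,
                   interactions = inputs$interactions %||% NULL,
                   omim = inputs$omim %||% NULL)
  digests <- as.list(tools::md5sum(unname(input_files)))
  names(digests) <- unname(input_files)
  counts <- list()
  stage <- function(name, code) {
    polyq_log(name, "starting")
    tryCatch(code, error = function(e) {
      abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)),
            class = "polyq_stage_error", parent = e)
    })
  }

  catalog <- stage("read", read_association_table(inputs$catalog, config))
  counts$catalog <- nrow(catalog)

  retained <- stage("scan", {
    r <- filter_by_l2g(catalog, config$l2g_cutoff)
    write_association_table(r, file.path(outdir, "scan_retained.tsv"))
    s <- summarize_scan(r)
    sweep <- threshold_sweep(catalog, config$sweep_grid)
    jsonlite::write_json(
      list(summary = unclass(s), sweep = sweep),
      file.path(outdir, "scan_summary.json"), auto_unbox = TRUE, digits = NA)
    r
  })
  counts$scan_retained <- nrow(retained)

  pri <- stage("prioritize", {
    p <- prioritize_catalog(retained, config)
    write_association_table(p$deduped, file.path(outdir, "prioritized.tsv"))
    anc <- summarize_ancestry(p$kept)
    jsonlite::write_json(
      list(report = p$report, ancestry = unclass(anc)),
      file.path(outdir, "prioritization_report.json"),
      auto_unbox = TRUE, digits = NA)
    p
  })
  counts$prioritized <- nrow(pri$deduped)

  if (!is.null(inputs$omim)) {
    stage("omim", {
      omim <- read_omim_table(inputs$omim)
      jsonlite::write_json(classify_omim_entries(omim),
                           file.path(outdir, "omim_classes.json"),
                           auto_unbox = TRUE, digits = NA)
      counts$omim_entries <- nrow(omim)
    })
  }

  if (!is.null(inputs$ld) && nrow(pri$deduped) > 0) {
    haps <- stage("signals", {
      ld_by_gene <- lapply(inputs$ld, read_ld_matrix)
      h <- identify_signals(pri$deduped, ld_by_gene, config$r2_cutoff)
      readr::write_tsv(flatten_haplotypes(h),
                       file.path(outdir, "haplotypes.tsv"),
                       na = ".", progress = FALSE)
      h
    })
    counts$haplotypes <- nrow(haps)
  } else {
    counts$haplotypes <- 0L
  }

  net <- stage("network", {
    n <- build_network(retained)
    export_network(n, file.path(outdir, "network_edges.tsv"),
                   format = "edge_list_tsv")
    n
  })
  counts$network_edges <- nrow(net$edges)

  if (!is.null(inputs$features)) {
    stage("profile", {
      profiles <- read_gene_features(inputs$features, inputs$interactions)
      verdicts <- aggregate_scores(profiles, config)
      readr::write_tsv(verdicts, file.path(outdir, "risk_verdicts.tsv"),
                       na = ".", progress = FALSE)
      jsonlite::write_json(
        list(mean_score = round_half_up(mean(verdicts$safety_score), 1),
             n_genes = nrow(verdicts)),
        file.path(outdir, "risk_summary.json"), auto_unbox = TRUE, digits = NA)
      counts$profiled_genes <- nrow(verdicts)
    })
  }

  manifest <- list(
    tool = "polyqprofiler",
    version = as.character(utils::packageVersion("polyqprofiler")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$rng_seed,
    config = unclass(config),
    input_digests = digests,
    counts = counts
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  polyq_log("pipeline", "done: %d stage outputs in %s", length(counts), outdir)
  invisible(manifest)
}
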