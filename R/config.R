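#' Default regular expressions flagging count-based traits
#'
#' Count-based traits (e.g. blood cell counts) yield numerous non-specific
#' GWAS signals across the genome and are removed during prioritization.
#' The default list matches the token "count"/"counts" plus a short lexicon
#' of blood-cell terms; it is fully overridable through
#' [threshold_config()].
#'
#' @return Character vector of regular expressions (matched case-insensitively
#'   against normalized trait labels).
#' @export
default_count_trait_patterns <- function() {
  c(
    "\\bcounts?\\b",
    "erythrocyte", "leukocyte", "platelet", "neutrophil", "reticulocyte",
    "monocyte", "lymphocyte", "eosinophil", "basophil"
  )
}

#' Analysis thresholds and settings
#'
#' Bundles every tunable cutoff of the pipeline. Defaults follow the
#' published thresholds used for drug-target risk classification: gene-trait
#' pairs are retained at locus-to-gene score L2G > 0.5, index variants are
#' pruned into haplotypes at r^2 > 0.5, genes are constraint-unfavorable at
#' pLI > 0.9, and interaction-unfavorable with more than 10 partners at
#' molecular-interaction (MI) score > 0.42. All comparisons are strict
#' inequalities; values exactly at a cutoff are not retained/unfavorable.
#'
#' @param l2g_cutoff L2G retention cutoff in `[0,1]`.
#' @param r2_cutoff LD pruning cutoff in `[0,1)`.
#' @param pli_cutoff Constraint (pLI) cutoff in `[0,1]`.
#' @param mi_cutoff Interaction confidence (MI score) cutoff in `[0,1]`.
#' @param partner_cutoff Interaction partner count above which a gene is
#'   unfavorable (integer >= 0).
#' @param count_trait_patterns Regex list for count-based trait removal.
#' @param sweep_grid Strictly increasing L2G grid for the robustness sweep.
#' @param rng_seed Integer seed used by seeded generators downstream.
#' @return An object of class `threshold_config` (a named list).
#' @examples
#' cfg <- threshold_config()
#' cfg$l2g_cutoff
#' @export
threshold_config <- function(l2g_cutoff = 0.5,
                             r2_cutoff = 0.5,
                             pli_cutoff = 0.9,
                             mi_cutoff = 0.42,
                             partner_cutoff = 10L,
                             count_trait_patterns = default_count_trait_patterns(),
                             sweep_grid = seq(0, 1, by = 0.1),
                             rng_seed = 1L) {
  stopifnot(
    is.numeric(l2g_cutoff), length(l2g_cutoff) == 1, l2g_cutoff >= 0, l2g_cutoff <= 1,
    is.numeric(r2_cutoff), length(r2_cutoff) == 1, r2_cutoff >= 0, r2_cutoff < 1,
    is.numeric(pli_cutoff), pli_cutoff >= 0, pli_cutoff <= 1,
    is.numeric(mi_cutoff), mi_cutoff >= 0, mi_cutoff <= 1,
    is.numeric(partner_cutoff), partner_cutoff >= 0,
    is.character(count_trait_patterns) || length(count_trait_patterns) == 0,
    is.numeric(sweep_grid)
  )
  if (length(sweep_grid) > 1 && any(diff(sweep_grid) <= 0)) {
    abort("`sweep_grid` must be strictly increasing.", class = "polyq_config_error")
  }
  for (p in count_trait_patterns) {
    ok <- tryCatch({ grepl(p, "x"); TRUE }, error = function(e) FALSE,
                   warning = function(w) FALSE)
    if (!ok) {
      abort(sprintf("Invalid count-trait regex: '%s'", p),
            class = "polyq_config_error")
    }
  }
  structure(
    list(
      l2g_cutoff = l2g_cutoff,
      r2_cutoff = r2_cutoff,
      pli_cutoff = pli_cutoff,
      mi_cutoff = mi_cutoff,
      partner_cutoff = as.integer(partner_cutoff),
      count_trait_patterns = count_trait_patterns,
      sweep_grid = sweep_grid,
      rng_seed = as.integer(rng_seed)
    ),
    class = "threshold_config"
  )
}

#' Read a threshold configuration from a key-value file
#'
#' Accepts a JSON file mirroring the fields of [threshold_config()]; absent
#' fields fall back to the defaults.
#'
#' @param path Path to a JSON configuration file.
#' @return A `threshold_config` object.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(threshold_config))
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    abort(sprintf("Unknown configuration keys: %s", paste(extra, collapse = ", ")),
          class = "polyq_config_error")
  }
  do.call(threshold_config, raw)
}

#' @export
print.threshold_config <- function(x, ...) {
  cat("<threshold_config>\n")
  cat(sprintf("  L2G > %.2f  |  r2 > %.2f  |  pLI > %.2f  |  MI > %.2f, partners > %d\n",
              x$l2g_cutoff, x$r2_cutoff, x$pli_cutoff, x$mi_cutoff, x$partner_cutoff))
  cat(sprintf("  sweep grid: %s\n", paste(format(x$sweep_grid), collapse = " ")))
  cat(sprintf("  count-trait patterns: %d  |  seed: %d\n",
              length(x$count_trait_patterns), x$rng_seed))
  invisible(x)
}

#' Normalize a trait label
#'
#' Case-folds, trims, and collapses internal whitespace. This is the only
#' harmonization applied to trait labels throughout the pipeline: two labels
#' count as the same trait iff their normalized forms are identical (no
#' ontology mapping is attempted).
#'
#' @param x Character vector of trait labels.
#' @return Normalized character vector.
#' @examples
#' normalize_trait(c("  Celiac  Disease ", "celiac disease"))
#' @export
normalize_trait <- function(x) {
  stringr::str_squish(stringr::str_to_lower(x))
}

# Round half away from zero (the convention used for printed percentages,
# e.g. 9/41 -> 22.0%), avoiding banker's rounding.
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

# Stage-tagged logging to stderr.
polyq_log <- function(stage, msg, ...) {
  message(sprintf("[%s] %s", stage, sprintf(msg, ...)))
}
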