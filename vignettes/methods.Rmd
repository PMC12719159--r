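---
title: "Methods: profiling polyQ disorder genes from catalog snapshots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profiling polyQ disorder genes from catalog snapshots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyqprofiler)
```

`polyqprofiler` profiles the ten polyglutamine (polyQ) disorder genes from
snapshot tables: a gene-trait association catalog (one row per GWAS signal
with an L2G score and index variant), per-variant annotations, pairwise LD
matrices, per-gene feature tables, and OMIM-style phenotype entries. This
vignette explains what each stage computes, the tunable parameters and why
their defaults are what they are, the numerical conventions, what the
synthetic generators do and do not emulate, and the package's known
limitations.

## Inputs and conventions

All tables are UTF-8 TSV with a header and `"."` for missing values — the
common denominator of bioinformatics tooling, and diffable in version
control. Coordinates are 1-based GRCh38 positions. Genes are keyed on
symbol (with an optional Ensembl id carried along); duplicate symbols in a
feature table are rejected rather than merged. Trait labels are normalized
by case-folding and whitespace-collapsing only; no ontology mapping is
attempted, so two phrasings of the same concept count as distinct traits.
Uniqueness of association records is taken as
(study, gene, trait, variant); no cross-release reconciliation is done.

A record counts as *peer-reviewed* iff its `pubmed_id` is non-missing;
records without one carry a biobank-level source label (e.g. a FinnGen or
UK Biobank release). This makes the provenance filter a pure function of
the table rather than of any external lookup.

## Phenome scan

`filter_by_l2g()` keeps records with locus-to-gene score strictly greater
than the cutoff. The L2G score (0–1) quantifies the evidence that a
genome-wide-significant signal is attributable to a given gene; the
default cutoff of 0.5 is the conventional "more likely than not"
threshold. The inequality is strict everywhere in this package — at the
L2G cutoff, the LD cutoff, the pLI cutoff, the MI cutoff and the partner
count — so boundary values are never retained/unfavorable. This is one
consistent reading of thresholds phrased as "greater than"; it matters
only for records exactly at a cutoff, and `threshold_sweep()` (default
grid 0.0–1.0 in 0.1 steps) makes cutoff sensitivity explicit. The sweep is
defined as the record count of the filter at each grid point, so
monotonicity is a theorem, and the test suite checks the sweep against the
filter pointwise.

## Prioritization

Count-based traits (blood-cell counts and the like) are associated with
very many loci genome-wide and mostly add noise to a gene-centric profile.
There is no canonical definition of "count-based", so the rule is an
overridable regex list: the default matches the token `count`/`counts`
plus a short blood-cell lexicon (erythrocyte, leukocyte, platelet,
neutrophil, reticulocyte, monocyte, lymphocyte, eosinophil, basophil).
Matching is case-insensitive on normalized labels.

`dedup_traits()` keeps one record per (gene, normalized trait): the
highest-L2G record, ties broken by smaller GWAS p-value, then
lexicographically smallest variant id. The max-L2G rule retains the
best-supported signal for each trait; the full tie-break chain makes the
output invariant to input row order.

Ancestry is summarized per *study*, not per record: a study appearing in
many rows counts once, "exclusive" means a singleton ancestry set, and
percentages are recomputed from integer counts and rounded half-up to one
decimal (so 31/41 prints as 75.6).

OMIM-style entries are partitioned into Mendelian versus susceptibility
entries by a flag that must agree with the phenotype label (an entry is
susceptibility iff its label carries a "susceptibility to" designation);
CAG-repeat-related entries are tallied separately because they reflect the
repeat itself rather than potential on-target knockdown consequences.

## Independent signals (haplotypes)

GWAS index variants near a gene are often redundant reports of one
underlying signal. `prune_to_haplotypes()` groups them greedily on
pairwise r²: variants are walked in canonical order; the first unassigned
variant becomes a *tag*, and every later unassigned variant with
r²(tag, v) > 0.5 joins that tag's haplotype. The result partitions the
variants, every member is in LD with its tag, and tags are pairwise not in
LD — both invariants are asserted by property tests against an
independently written brute-force implementation of the same rule over all
LD matrices of up to six variants with entries in {0, 0.9}.

Three numerical choices deserve explanation:

* **Canonical order is position-first** (ascending position, ties by GWAS
  p-value, then id). Greedy clustering output depends on processing order;
  position order mirrors LD-pruning tools that retain the first variant of
  a position-sorted input list, and makes the tag of each haplotype the
  leftmost member. Haplotypes are then numbered per gene by ascending tag
  position.
* **Tag-centric membership, not transitive closure.** A variant joins a
  haplotype only if it is in LD with the *tag*, matching the "single tag
  variant as proxy" definition. In a chain a–b, b–c (a–c independent) this
  yields {a, b} and {c}, whereas single-linkage would merge all three; the
  tests document this difference explicitly.
* **Missing r² is treated as 0** (independence) with a logged warning.
  This is conservative toward declaring signals independent rather than
  silently merging them.

Whether the LD matrix was computed from an appropriate reference panel
(e.g. excluding populations with extended haplotype blocks) is a
data-provenance matter of the input, not a branch in the algorithm.

Variant consequences are ranked by a shipped severity table following the
conventional Ensembl VEP ordering (splice terms above UTR terms above
intronic); `most_severe()` rejects terms outside the vocabulary rather
than guessing.

## Shared-trait network

`build_network()` counts, for every unordered gene pair, the distinct
normalized traits both genes are associated with. Edges require at least
one shared trait and are weighted by the shared-trait count — association
rows are deduplicated to trait sets first, so the network is invariant to
duplicate records and row order. Correlated but distinct trait labels
(e.g. two phrasings of educational attainment) deliberately count
separately; collapsing them would require an ontology the inputs do not
carry. Edge weights are verified against a brute-force per-trait
pair-counting oracle on random catalogs.

## Risk profiling

Three gene-level features are associated with clinical-trial stoppage for
safety reasons, and each contributes one point to a 0–3 *safety score*:

| feature | unfavorable when | default cutoff |
|---|---|---|
| genetic constraint | pLI strictly above cutoff | 0.9 ("extremely LoF-intolerant") |
| tissue expression | HPA class is "low tissue specificity" | — |
| molecular interactions | more than `partner_cutoff` partners with MI score strictly above `mi_cutoff` | 10 partners, MI 0.42 |

A missing feature is *unknown* and contributes nothing (the fixtures have
complete data, so no imputation rule is needed); the verdict columns keep
unknowns visible. The druggable-any indicator is carried through but never
scored — it marks theoretical perturbability, not safety.

Gene sets are compared with a two-sided Wilcoxon/Mann–Whitney rank-sum
test on mid-ranks. The default method uses the tie-corrected normal
approximation without continuity correction (checked in the tests against
`wilcox.test(correct = FALSE)`); an exact method enumerates all
assignments of the pooled values to groups (feasible for n₁ + n₂ ≤ 12)
and computes the permutation p-value P(|U − μ| ≥ |U_obs − μ|). The effect
size is r = |z|/√n with the conventional 0.1/0.3/0.5 labels. When all
pooled values are identical the comparison is degenerate and reported as
z = 0, p = 1.

One caution, established by exhaustive enumeration over all integer-score
inputs with group sizes ≤ 6 and values in 0–3: the normal approximation
can deviate from the exact p by as much as ~0.68 for tiny, tie-heavy
groups (the worst cases are near-degenerate score patterns with large
p-values). In the decision-relevant region (exact p ≤ 0.1) the deviation
stays below 0.08 in that sweep. Safety scores are small integers with
heavy ties, so for groups this small the exact method is the one to
trust; the tests assert the exact method agrees with an independent
enumeration oracle to machine precision.

## Synthetic data and fixtures

`generate_catalog()` emulates the *structure* of a gene-trait catalog
snapshot: planted pair-shared traits (realized sharing equals the spec
exactly, with no accidental sharing outside the planted pairs), a Poisson
number of gene-specific traits per gene, a binomial fraction of records
above the L2G cutoff and lacking PubMed ids, and synthetic study/variant
identifiers. It does not emulate ontology structure among trait labels,
LD between the variants of different records, realistic effect-size or
allele-frequency distributions, or cross-study heterogeneity — so tests
passing on synthetic catalogs validate the bookkeeping and the algorithms'
contracts, not the biology of real catalogs.

`generate_ld_blocks()` generates r² directly (no genotypes or phasing):
within-block entries sit at `within_r2` ± 0.05 of uniform jitter, clipped
to stay strictly above the pruning cutoff, and between-block entries at
`between_r2` ± 0.05 clipped to stay at or below it. The clipping is what
guarantees deterministic block recovery, including at boundary settings
like within-r² = 0.51 against a cutoff of 0.5. Both generators save and
restore the global RNG state, so they are pure functions of their spec.

The packaged fixtures encode the study conditions the pipeline is
demonstrated on: a 38-row catalog of high-confidence associations for
five polyQ genes over 29 index variants in 21 haplotype blocks
(within-block r² around 0.8, between 0.1); a 215-record provenance
catalog in which exactly 32 records (4 FinnGen, 26 UK Biobank Neale lab,
2 UK Biobank SAIGE) lack PubMed ids; a 10-gene feature table in which
only THAP11 has ≤ 10 high-confidence interactors, only AR and CACNA1A
are tissue-restricted, and five genes (ATN1, ATXN1, ATXN7, HTT, and
CACNA1A) are constraint-unfavorable; a 12-entry OMIM-style table
(8 Mendelian, 4 susceptibility, 4 CAG-related); and a 41-study ancestry
table (31 exclusively European). Two fixture fields are assumptions
rather than transcriptions: the identity of the fifth
constraint-unfavorable gene (assigned to CACNA1A) and the membership of
the druggable-any set (AR, ATXN1, ATXN2, CACNA1A, HTT) — the aggregate
mean safety score of 2.2 is invariant to both. Genomic positions, study
identifiers, PubMed ids, ancestry labels and all LD values in the
fixtures are synthetic placeholders; positions are assigned so that each
haplotype's variants are contiguous with the tag leftmost. The shipped
TSVs under `inst/extdata/` regenerate bit-identically from
`write_fixture_files()`.

## Problem sizes in the test suite

The property suite runs exhaustively where enumeration is cheap: all
~33k LD patterns over ≤ 6 variants for the pruning oracle, all ~28k
score-multiset pairs with group sizes ≤ 6 for the rank-sum oracle, and
1,000/500 seeded random catalogs for the sweep and network oracles. These
sizes keep the full suite in the low minutes on a single CPU while still
covering the combinatorial space the algorithms branch on.

## Limitations

* The package consumes L2G, CADD, pLI, HPA classes and MI scores as
  annotation columns; it never recomputes them, and its conclusions
  inherit whatever biases those upstream resources carry.
* Catalog-scale figures (thousands of signals across hundreds of traits)
  require a live catalog snapshot; the packaged fixtures cover the
  gene-level facts and the algorithms' contracts, not catalog-scale
  counts.
* Comparison gene sets (e.g. disease-modifier genes) must be supplied as
  feature tables by the user; none are packaged.
* Trait identity is string-normalized only; cross-catalog harmonization
  of trait labels is out of scope.
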