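---
title: "Determining the y-ome: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining the y-ome: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A large fraction of the genes in even the best-studied bacterium lack
experimental evidence of function: annotations say "predicted transporter"
or "hypothetical protein", or say nothing at all. We call the set of genes
without experimental, mechanistically grounded evidence of function the
**y-ome**, after the naming convention that gives unannotated *E. coli*
open reading frames primary names starting with "y". Name and annotation
status have drifted apart — many 'y'-named genes are now well characterized
and many poorly characterized genes carry ordinary names — so the y-ome has
to be determined from annotation *content*, not from names.

No single knowledge base is sufficient: organism encyclopedias, protein
databases and regulatory databases each capture different evidence. This
package implements a reproducible workflow that integrates several sources
and then characterizes the resulting gene set.

## The workflow

1. **Ingest** (`ingest_kb_tables()`): per-source dumps normalized to a
   canonical TSV (`kb, locus_tag, primary_name, synonyms, feature_type,
   feature_value`) are parsed into a feature store, and a unique-gene
   registry is resolved across sources. Identity precedence is locus tag >
   exact primary-name match > synonym match: locus tags are the only
   stable cross-source key. When sources disagree about a primary name the
   locus tag wins, the name from the highest-precedence source becomes
   primary and the rest become synonyms; every such decision lands in the
   merge log. Genes seen in only one source are kept — sparsity is handled
   downstream by the consensus stage, not by dropping records at ingest.
2. **Per-source categorization** (`categorize_store()`): a data-driven rule
   engine assigns each gene one of *y-ome*, *well-annotated*,
   *insufficient information* or *excluded* per source. Keyword rules
   (case-insensitive; substring by default, word-boundary mode per rule,
   because low-annotation wording appears inflected) mark low-annotation
   text ("possibly", "predicted", "hypothetical") and assay-grade evidence
   phrases; structured rules handle annotation scores (≤2 y-ome, 3
   insufficient, ≥4 well-annotated), reaction equations, complex
   membership, insertion elements (including "ins"-prefixed encyclopedia
   names), pseudogene/phantom flags and the apostrophe-suffix pseudogene
   convention. Within one source, fired rules resolve by the precedence
   *excluded > well-annotated > y-ome*; nothing fired means insufficient.
   The shipped rule set (`inst/extdata/rules.yaml`) is deliberately
   config, not code: real knowledge-base releases need extended lists, and
   cryptic genes intentionally receive no special rule — phenotypic
   silence does not remove a gene from the y-ome.
3. **Consensus** (`apply_consensus()`, `finalize()`): per-source votes
   combine in a fixed evaluation order — exclusion first (the
   pseudogene/phantom track is separate and cannot be resurrected by
   evidence rules), then four well-annotated exceptions (assay-grade
   encyclopedia evidence; "Strong" transcription-factor evidence;
   encyclopedia and protein database both well-annotated; insertion
   elements), then agreement among all definite votes, then the manual
   override layer for genuine disagreements. "Agreement" is generalized
   to: at least one definite vote and all definite votes identical. A gene
   with only insufficient votes defaults to the y-ome with a
   low-confidence flag — absence of evidence is precisely the y-ome's
   definition. An open design point: assay-grade evidence *can* override a
   low-annotation keyword from the same source; the evaluation order above
   makes that explicit. Two conventions worth noting: the basis enum has no
   separate "excluded" value, so decisive exclusion is recorded with basis
   `agreement`; and in permissive (non-strict) mode uncovered unresolved
   genes pass through as y-ome while *keeping* basis `unresolved` as a
   visible flag — strict mode, the reproducible default, refuses to
   finalize instead.
4. **No-information flag** (`detect_no_info()`): a gene is flagged when
   every scanned piece of content is empty, begins with a stock phrase
   ("No information about this", "Putative uncharacterized"), or is a
   domain/family-only annotation. Domain-only genes stay in the y-ome: a
   domain of unknown function is not functional evidence.
5. **Analyses**: expression stratification, circular chromosome density,
   co-expression module composition, term frequency, and the 'y'-name
   crosstab (below).

## Analysis methods and parameter choices

**TPM and log-TPM.** TPM is computed in-repo from a counts matrix with the
standard definition (length-normalized rate rescaled to 1e6 per sample) —
a deliberate substitution for pipeline-specific upstream quantification,
which is out of scope here. All analysis happens on log2(TPM + 1).

**Replicate QC.** Replicate groups are compared by pairwise squared
Pearson correlation of log-TPM; a group whose minimum pairwise R² falls
below 0.9 is removed *as a group* — removal of single members would leave
an arbitrarily chosen survivor. Single-replicate conditions are retained
and flagged as not assessable.

**Mean expression.** Replicates average within condition first, then
across conditions, so unevenly replicated conditions weigh equally. The
mean is across conditions (not samples) because the compendium design is
condition-structured.

**Category contrast.** Welch's unequal-variance two-sample t-test on mean
log-TPM, y-ome vs well-annotated (the statistic is negative when the y-ome
is lower). Equal variances are not assumed because the two categories
differ in composition, not only in mean.

**Percentile threshold.** "Top 20% of expression" uses the empirical-CDF
linear-interpolation quantile (R type 4) and takes genes strictly above
the threshold. The convention is pinned and documented because percentile
cutoffs on real compendia cannot be re-derived without the identical data;
on the values 1..10 the top-20% threshold is 8 and the slice is {9, 10}.

**Circular density.** Gene start sites (1-based, forward-numbered; the
biological start — left end on the plus strand, right end on the minus
strand; strand recorded but otherwise unused) map to angles
2π(start−1)/L. The density estimator is a von Mises kernel:
f(θ) = (1/n) Σᵢ exp(κ·cos(θ−θᵢ)) / (2π·I₀(κ)). κ is configuration
(default 50, a smoothing window of a few hundred kb on a ~4.6 Mb circle)
because no principled bandwidth is available for this application; results
that depend on κ should be read qualitatively. Evaluation is on a 1024-
point regular grid; every returned density is checked to integrate to 1
(periodic trapezoid, tolerance 1e-6) and κ=0 reduces exactly to the
uniform density 1/(2π). Origin/terminus positions default to the
documented replication-origin coordinate of the reference assembly and its
antipode; `region_enrichment()` reports per-window gene fractions and the
terminus/origin ratio per category, with undefined ratios (empty origin
window) reported as NA rather than invented.

**Modules and candidates.** Module detection itself is consumed from an
external weighted-correlation network tool's gene→module table, never
re-implemented. y-ome candidates rank by the fraction of well-annotated
co-members, then module size, then gene id — a deterministic total order.

**Term frequency.** Whole-word matching after tokenization on
non-alphanumerics; substring matching would conflate "transport" with
"transporter", which the word-set grouping handles explicitly. A gene
counts at most once per word set. Scanned feature types (default:
description, summary) are configuration.

**Summary percentages** round half-up to one decimal. On the worked
example of 1600 / 2803 / 220 over 4623 genes this gives 34.6% / 60.6% /
4.8%; note that 220/4623 can also be seen printed as 4.7% under a
different rounding, which this package does not emulate.

## The synthetic-data generator

`synthetic_spec()` + the `generate_*()` functions produce every pipeline
input with planted ground truth. Defaults are the study conditions: the
category fractions above, 111/1600 no-information rate, a 2 log2-unit
y-ome expression deficit against a well-annotated mean of 6 with unit
between-gene spread, terminus concentration 2 for y-ome starts, and
modules of size ≥ 10. Replicate noise defaults to 0.25 log2 units
(replicate R² ≈ 0.97, typical biological-replicate reproducibility);
analyses that stress the contrast under heavier noise pass sigma
explicitly. Counts are rounded length-scaled log-normal draws — enough
for the category-contrast statistics exercised here, not a full RNA-seq
error model (no overdispersion structure, library-size variation, operon
correlation or sequence content). Category counts are exact at any n via
largest-remainder apportionment. Conflicted genes carry only a
contradictory vote pair (low-annotation description vs high annotation
score, chosen so no exception heuristic can short-circuit the
disagreement) plus a generated override, so recovery through the manual
layer is testable. All generators are deterministic given the spec seed
(byte-identical files).

What passing tests on synthetic data do show: the rule engine, consensus
logic, override routing, normalization, density estimation and counting
analyses are correct against independent oracles and planted truth. What
they do not show: that the shipped keyword lists are complete for any real
knowledge-base release, or that real expression/position effects match the
planted effect sizes — those are properties of the data, not the code.

## Problem sizes

The shipped tests run the consensus oracle over all 5⁴ per-source state
combinations and all 2¹² rule subsets, planted-label recovery at 1000
genes × 20 seeds (clean and with 10% conflicts), the expression contrast
at 300 genes per category over 100 seeds (plus 200 null seeds), and
density checks at up to 10⁴ points. `scripts/acceptance.R` recomputes the
same quantities at 5 seeds for recovery and the full seed counts for the
statistical checks.

## Known limitations

- Keyword rule sets ship with the documented core phrases only and are
  meant to be extended per knowledge-base release.
- The apostrophe pseudogene convention, annotation-score semantics and
  evidence phrasing are source-specific conventions encoded as defaults;
  other organisms/databases will need their own rule configuration.
- The feature store is a plain-TSV table store; it holds this workflow's
  scale (thousands of genes) comfortably but is not a concurrent database.
- GenBank reading covers the flat-file subset needed for gene start
  extraction (LOCUS length, `gene` features, locus_tag/gene qualifiers).
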