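---
title: "Origin-aware integration of microbiome and metabolome data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Origin-aware integration of microbiome and metabolome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaborigin)
library(dplyr)
```

## The problem

A stool metabolome is a mixture of signals: compounds synthesized by the
host, compounds produced or transformed by gut microbes, compounds both
can handle, and compounds that arrive with food, drugs or environmental
exposure. Pooling all of them into one pathway-enrichment run against a
host-centric pathway library blurs these sources together — a microbial
pathway can never look enriched against a human reference, and a pooled
human-plus-microbe reference double-counts overlapping pathways.
`metaborigin` makes the origin of each metabolite a first-class quantity
and carries it through every downstream step: enrichment is run
separately per origin against that origin's own reference universe,
taxon–metabolite correlations are overlaid on the reaction network, and
the biological ("which organisms could do this reaction?") and
statistical ("which taxa actually co-vary with this metabolite here?")
views are rendered as dual Sankey diagrams.

## Origin classification

Metabolites are matched against an offline knowledge base by KEGG ID,
then HMDB ID, then exact normalized name or synonym (case, whitespace
and punctuation are ignored; identifiers always beat names, and a
KEGG/HMDB conflict resolves to KEGG with a warning). The matched entry's
origin evidence is a subset of seven tags — mammal, archaea, fungi,
bacteria, food_plant, drug, toxin_pollutant — and the category rule is:

* mammal **and** any microbial tag → **Co-Metabolism**
* mammal only (among biological tags) → **Host**
* microbial tags only → **Microbiota**
* otherwise the first of **Food** > **Drug** > **Environment** present
* no evidence, or no match → **Unknown**

The Food > Drug > Environment precedence is a tie-break convention of
this package: the six groups themselves do not define an order for
compounds annotated with several non-biological sources, and making the
choice deterministic matters more than which order is chosen.

The knowledge base itself is built by [merge_sources()] from per-database
source records. Two records are the same compound when they share a KEGG
ID, share an HMDB ID, or agree on normalized formula *and* at least one
normalized name; identity is closed transitively over these links
(connected components). Formula alone is deliberately not enough —
isomers share formulas — and name alone is not either, since synonym
lists are noisy across databases. When merged records disagree on
formula, all formulas are retained and the KEGG-sourced one is treated
as canonical.

```{r classify}
kb <- phenylalanine_kb()
queries <- tibble::tibble(
  name = c("phenylalanine", "Benzoate", "caffeine"),
  kegg_id = "", hmdb_id = "")
classify_origins(match_metabolites(queries, kb), kb)
```

## Origin-scoped pathway enrichment

For a scope (host organism, the microbial community, or both) the
reference library collects every pathway carried by the scope's
organisms; the **universe** is the union of those pathways' member
metabolites — metabolites belonging to no pathway of the scope are not
part of the population, mirroring the idea that the test compares "in
this pathway" against "in the other pathways". For a pathway with `m`
members in a universe of `m + n`, and `k` mapped differential
metabolites of which `q` hit the pathway, the p-value is the upper tail

$$p = P(X \ge q), \qquad X \sim \mathrm{Hypergeom}(m + n,\, m,\, k),$$

computed directly as `phyper(q - 1, m, n, k, lower.tail = FALSE)` rather
than `1 - phyper(q - 1, ...)`, which avoids catastrophic cancellation
when p is small. Differential metabolites that do not map to the
universe are excluded from `k` and reported separately. Only pathways
with at least one hit are returned; the significance flag uses raw
p ≤ α (default 0.05) with Benjamini–Hochberg available as an option —
raw-p thresholding is the default because origin-scoped universes at
this scale are small and the per-scope pathway counts low.

Two pooled comparison modes (`all_host`, `all_cometabolism`) reuse the
host and combined universes but take *all* differential metabolites;
they exist to reproduce the classic analysis the origin-split approach
improves on, so the difference is visible on the same data.

Pathway topology weighting (degree/betweenness-based impact scores) is
intentionally out of scope: only the hypergeometric component is
implemented.

## Taxon–metabolite association

Taxa tables arrive at species level as prefixed lineage strings
(`p__…|c__…|…|s__…`); coarser ranks are produced by summing child
abundances. Spearman (default) and Pearson coefficients come with
two-sided t-approximation p-values; pairs with a constant vector are
reported as degenerate (coefficient 0, p = 1) instead of failing.
Samples are aligned by strict ID intersection — at least 3 shared
samples are required and a warning fires when more than half mismatch.

The maximal information coefficient is provided as a documented
approximation: equal-frequency grids of shape (i, j) with
`i·j ≤ n^0.6` (each axis capped at 15 bins), mutual information
normalized by `log2(min(i, j))`, maximized over shapes. This saturates
at 1 for noiseless functional relationships and stays near 0 under
independence, but can underestimate dependence whose optimal partition
is far from equal-frequency; since MIC has no analytic null, its p-value
is a seeded permutation p (default 200 permutations).

## The two Sankey views

For every reaction of a significant pathway touched by a differential
metabolite, two diagrams share one layout — metabolite column, enzyme
column, then phylum → class → order → family → genus → species:

* **Bio-Sankey**: the background is every organism the knowledge base
  lists for the reaction, in gray; link widths count the distinct
  species beneath each taxonomy branch (so widths are conserved across
  every taxonomy column boundary — each species contributes exactly one
  unit). When correlations are supplied, the link into a taxon
  significantly correlated with the substrate or product turns
  red/green by sign and is emphasized.
* **STA-Sankey**: the dual — the background is every taxon
  significantly correlated with the substrate or product, colored by
  sign, and a taxon is emphasized when it *also* appears in the
  knowledge base's organism list for the reaction. "Correlated with
  either substrate or product" (not both) is the inclusion rule; when a
  taxon correlates with both, the larger |coefficient| decides the
  color.

Several enzymes can catalyze one reaction in different organisms; each
enzyme gets its own node and organisms connect through their own
enzyme. Within a column, nodes are ordered by descending band width,
then label, so output is deterministic.

```{r sankey, fig.width = 7, fig.height = 4}
g <- build_bio_sankey("R00693", kb)
glance(g)
autoplot(g)
```

Per-origin summary networks condense the result: diamond metabolite
nodes (differential members of the origin's significant pathways,
colored by regulation), dot taxon nodes, and edges only where the
correlation p ≤ 0.01 — a stricter default than the Sankey overlay
because the summary is meant to show only the strongest cross-talk.
Host-origin summaries are metabolite-only by construction. Graphs
export to a documented JSON schema (lossless round trip), GraphML and
standalone HTML.

## Pretreatment choices

Missing metabolite intensities are assumed left-censored; four
imputation rules are offered. `min` (the default in the pipeline)
substitutes the per-feature observed minimum — transparent and
deterministic; `knn` averages the k nearest feature profiles; `rf`
refines a minimum-imputed start with iterative random forests
([ranger]); `qrilc` fits the observed order statistics against normal
quantiles and fills the censored tail with the fitted sub-detection
quantiles. All stochastic methods are seeded; observed values are never
modified. Normalization is `log10(x + pseudo-count)` (pseudo-count:
half the smallest non-zero value, applied only when zeros are present)
or per-sample total-sum scaling to 100.

The differential test defaults to the two-sided Mann–Whitney U because
it behaves sensibly for both metabolite intensities and compositional
relative abundances; Welch's t-test is available. The effect size is the
log2 ratio of group means of the *processed* values, "case" over
"control" in the order groups appear in the sample table; a zero
difference reports direction "up" by convention and can never be
flagged significant. Raw-p thresholding at α = 0.05 is the default to
match the per-origin reporting convention, with BH as an option.

## What the synthetic data emulate — and what they do not

`generate_kb()` builds a miniature knowledge base: organisms with
complete six-rank lineages (bacterial phyla drawn from a realistic
pool), metabolite entries per origin category created by pushing
synthetic source records through the real deduplication code, and
pathways with guaranteed host-only, bacteria-only and shared occurrence
patterns so every reference scope is non-trivial. Defaults — 12
bacteria across 3 phyla, 43 metabolites (10 host, 16 microbiota, 10
co-metabolism, 7 food/drug/environment), 8 pathways of 4–8 members,
3 reactions each — were chosen once so that a fully differential
pathway is resolvable against its scope's universe at conventional α,
which is the regime the method is designed for.

`generate_study()` draws log-normal metabolite intensities (sdlog 0.5)
with multiplicative case-group shifts for planted differential
metabolites, and species-level Dirichlet-multinomial counts
(concentration 5, depth 50 000 — moderate overdispersion typical of
16S data). A planted (species, metabolite) correlation shares a latent
Gaussian factor between the metabolite's log-intensity and the
species' log-concentration; the loading solves
\(c^2/(1+c^2) = \rho^\*\) on the latent scale, with
\(\rho^\* = \min(0.98,\ 1.04\,\rho)\). The 1.04 factor is a calibration
constant measured once by Monte-Carlo against the realized Spearman
correlation (counting noise and the rank transform attenuate the latent
correlation) and frozen; across targets 0.6–0.9 the realized mean sits
within ±0.02 of the target. Missing values are injected completely at
random, and the default missing rate is 0 — missingness is opt-in so
that each test controls exactly one difficulty at a time.

Deliberately not emulated: phylogenetic correlation between taxa, batch
effects, zero-inflation beyond the Dirichlet-multinomial, non-random
missingness, and identifier noise beyond typographic synonym variants.
Passing tests on these fixtures therefore demonstrate the correctness
of the accounting — classification, universes, tail probabilities,
widths, round trips — and the recoverability of planted structure at
realistic effect sizes; they do not certify behavior under real-data
pathologies like compositional spurious correlation, which the
correlation module does not attempt to correct (SparCC-style methods
are out of scope).

## Numerical and degenerate-input conventions

* Hypergeometric p-values are exact tail calls; tests verify them to
  1e-10 against plain binomial-coefficient summation over all
  populations up to 60.
* Constant features/vectors: differential p = 1 and effect 0;
  correlation coefficient 0 and p = 1, flagged `degenerate`.
* A reaction without lineage-bearing organisms yields a
  metabolite-and-enzyme-only graph; an STA-Sankey with no significant
  taxon warns and degrades the same way.
* All randomness is seeded through one RNG helper that restores the
  caller's RNG state; derived stream seeds stay below 2^31.
* Name matching everywhere (synonyms, taxa, correlation overlays) uses
  one normalization: case-fold and strip non-alphanumerics.

## Problem sizes used in the test suite

The suite exercises the full pipeline on the default miniature
conditions: knowledge bases of ~43 metabolites / 16 microbes, studies
of 15 samples per group, 100-seed recovery loops for the planted
bacteria-only pathway (log2 fold change 2) and planted ρ = 0.8 pairs,
1000-feature null-calibration runs, and 100 random reactions for the
Sankey conservation audit. These sizes keep each property statistically
meaningful while the whole suite stays in the minutes range on one CPU.

## Known limitations

* MIC is an equal-frequency-grid approximation, not the exact
  dynamic-programming optimization.
* Correlations are plain pairwise associations on (optionally
  normalized) abundances; compositionality is not corrected.
* Rank-level correlation taxa are matched to species-resolved organism
  lists by normalized name at the table's rank, so genus-level evidence
  emphasizes a genus node even when the correlated species is not the
  listed one.
* The knowledge base ships no real database content; real analyses
  require building a bundle from licensed sources in the documented
  TSV-plus-manifest format.
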