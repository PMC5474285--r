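---
title: "Methods: the herbnet network-pharmacology pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the herbnet network-pharmacology pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbnet)
```

## The problem

A single herbal preparation contains dozens of phytochemicals, each of
which may bind many protein targets. Network pharmacology asks whether
the preparation, taken as a system, is plausibly connected to a disease:
which of its compounds are pharmacologically viable, which proteins they
collectively reach, how that compound--target network is organized, which
biological processes and pathways the targets over-represent, in which
organs the targets are expressed, and whether the targets overlap genes
actually dysregulated in patient tissue. herbnet implements that chain of
analyses as composable, deterministic R functions, with the published
screen of *Pulsatillae Radix* (a root preparation used for dysentery and
inflammatory bowel conditions) against Crohn's disease packaged as its
worked fixture set.

## ADME screening

Compounds are screened on three predicted absorption/distribution axes:

* **Oral bioavailability (OB)**, in percent: the predicted fraction of an
  oral dose reaching systemic circulation. Default threshold 15%.
* **Caco-2 permeability**, dimensionless: predicted intestinal epithelial
  permeability from the Caco-2 cell model. Default threshold -0.4.
* **Drug-likeness (DL)**, dimensionless: the continuous Tanimoto
  similarity between a compound's molecular-descriptor vector $A$ and the
  average descriptor vector $B$ of a reference drug database,
  $$F(A,B) = \frac{A \cdot B}{|A|^2 + |B|^2 - A \cdot B},$$
  which lies in $[0,1]$ for nonnegative descriptors. Default threshold
  0.18.

`dl_tanimoto()` implements $F$ for users who hold descriptor vectors; the
packaged compound table consumes DL values as published (one value,
-2.18, falls outside $[0,1]$, which is why no unit-interval bound is
enforced on stored DL columns; signed descriptor components can produce
such values and the table is kept verbatim).

Two deliberate choices in `apply_adme_filter()`:

* **Comparisons are inclusive (`>=`) by default.** The source material
  states the criteria both as strict and as inclusive in different
  places; the inclusive reading is adopted as the default because it is
  the form used when the criteria are stated together with their final
  compound list, and a flag (`inclusive = FALSE`) flips to strict. On the
  packaged table the two readings give the same partition.
* **Rescue is an explicit input, not a heuristic.** Single-herb studies
  commonly retain threshold-failing compounds with independent
  experimental support. The 14 packaged rescue ids (`pr_rescue_ids()`)
  are exactly the compounds in the packaged table that fail the default
  thresholds; the filter refuses rescue ids absent from the input, so a
  typo cannot silently become a no-op. The report always partitions the
  input: `passed`, `rescued` and `excluded` are disjoint and exhaustive,
  and excluded compounds carry every violated criterion.

Evaluating the packaged 32-compound table under the default thresholds
yields 18 passes; with the rescue list all 32 are retained. (The study
the fixtures come from quotes 19 passing compounds out of its original
57-compound database query; evaluating the printed 32-row table itself
gives 18, and herbnet reports its own arithmetic rather than the quoted
count.)

## Target catalog

`merge_interactions()` treats compound--target interaction tables from
different databases (e.g. TCMSP, SEA, BindingDB exports) as sources of
presence/absence evidence: the merged catalog is the set union of
(compound, target) pairs, each retaining the sorted union of source
labels. Merging is idempotent and order-invariant. Accessions that fail
to resolve against the supplied target table are kept in the edge list
but reported in `unresolved` — dropping them silently would bias degree
counts, and failing hard would make the catalog hostage to database
identifier drift. Downstream gene-level operations key on gene symbols
(uppercased at ingest) rather than accessions, because expression and
differential-expression resources are symbol-keyed.

The headline statistic `average_targets_per_compound()` is the number of
*distinct* targets divided by the number of compounds, reported to one
decimal — 182 targets over 32 compounds gives 5.7.

## Networks and centrality

All networks are bipartite, undirected and unweighted (the underlying
evidence has neither direction nor reliable weights): compound--target,
target--pathway, and organ--gene. `build_bipartite()` validates
partition membership, rejects within-partition edges and self-loops, and
keeps declared isolated nodes, so degree-0 entities remain visible in
exports.

Centrality uses igraph: degree, and Brandes shortest-path betweenness
with endpoints excluded. Normalized betweenness divides by
$(N-1)(N-2)/2$ where $N$ is the full node count of the graph — the
convention of the Cytoscape/NetworkAnalyzer tooling that this class of
study reports — and the same divisor is used for disconnected graphs.
Graphs with fewer than three nodes report zero rather than dividing by
zero. The test suite cross-checks igraph's values against an independent
all-pairs shortest-path enumeration oracle on hundreds of random small
graphs. Whether a published study computed betweenness per network or on
a merged graph is usually unstated; herbnet computes it per network in
isolation.

Rankings (`rank_nodes()`) sort descending with lexicographic tie-breaks,
so output is reproducible even when many nodes share a degree.

## Over-representation analysis

`run_enrichment()` is a replacement for web annotation tools: the
upper-tail hypergeometric test
$P(X \ge k)$ for an overlap of $k$ query genes with a $K$-member set in
an $N$-gene universe and an $n$-gene query, computed through the stable
distribution function rather than naive summation, with the EASE variant
(one overlap member removed, `ease_score()`) available opt-in because
annotation portals differ in which they use. Raw p-values over the whole
collection are Benjamini--Hochberg adjusted; filtering applies to the
**raw** p-value at the default 0.01 cutoff with both columns reported,
since published workflows are frequently ambiguous about which value
they thresholded. The universe defaults to the union of collection
members — the least presumptuous background when none is stated — and
can be supplied explicitly. Results are invariant to query order and
duplication.

`map_to_pathway()` is the final mapping step: partitioning target genes
by membership in one curated pathway (e.g. the KEGG inflammatory bowel
disease map supplied as a GMT line). Curated disease-pathway lists are
inputs, not inferences.

## Organ localization

The organ-location statistic is a threshold rule, not a test: for each
gene, compute the mean expression across **all** tissues of the atlas
(e.g. 84), then call the gene in a tissue iff its expression there
strictly exceeds that mean. Summaries (per-organ frequency,
at-least-$k$-organs, all-panel-organs, the organ--gene network) are then
taken over a configured organ panel — the packaged default is the 17
immunity-related tissues (`pr_organ_panel()`). Two consequences of the
strict rule are worth noting: a constant gene is called nowhere, and no
gene can be called in every tissue of the full atlas (though it can be
called in every *panel* tissue). The mean-over-all/report-over-panel
ordering follows the procedure's stated steps; computing the mean over
the panel alone would systematically inflate calls in tissue-restricted
genes.

Atlas matrices are probe-keyed in the wild; `collapse_probes()`
aggregates probes per gene by `max` (default — conservative for
presence calls, since any probe above the mean indicates expression) or
`mean`. A gene observed in a single tissue has an undefined call (its
mean equals its value) and is rejected.

## Differential expression

`moderated_t()` implements the empirical-Bayes moderated t statistic
that GEO's two-group interface popularized: gene-wise pooled variances
$s_g^2$ on $d = n_1 + n_2 - 2$ degrees of freedom are shrunk toward a
prior $s_0^2$ with weight $d_0$,
$$\tilde{s}_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d},
\qquad t_g = \frac{\bar{x}_{g,\mathrm{disease}} - \bar{x}_{g,\mathrm{control}}}
{\tilde{s}_g \sqrt{1/n_1 + 1/n_2}},$$
with two-sided p-values on $d_0 + d$ degrees of freedom. At $d_0 = 0$
this is exactly the ordinary pooled t test (verified to $10^{-10}$ in
the suite); as $d_0 \to \infty$ every variance collapses to the prior.
`estimate_prior()` fits $(d_0, s_0^2)$ by method of moments on
$\log s_g^2$ under the scaled-F model, inverting the trigamma function
by Newton iteration; $d_0$ is capped at 100, beyond which moderation is
numerically complete, and literally constant variances short-circuit to
the cap with the common value as prior. The suite cross-checks both the
statistics and the prior fit against limma on the same data.

"Highly expressed in the disease group" is read as a positive-direction
filter (`mean_diff > 0`) applied **before** ranking by ascending p-value
and truncating to the top $n$ (default 250); `direction = "both"`
disables the filter, since exported top tables from web tools mix
directions. Ties break by descending $|t|$ then gene id. Per-dataset top
lists are pooled by `union_dedupe()` (set union after symbol
normalization) and intersected with the target symbols by
`intersect_targets()`, optionally annotated from the target table.
Reproducing a specific published intersection requires the original
accession downloads and is inherently sensitive to top-$n$ boundary
drift across tool versions; the machinery is therefore validated on
planted synthetic overlaps (sizes 0, 5 and 23 recovered exactly) rather
than on live downloads.

## Synthetic data: what it does and does not show

The generators exist so every stage has inputs with known ground truth:

* `gen_compound_table()` draws OB from a log-normal (median 20%, log-sd
  0.7), Caco-2 from a normal (mean 0.5, sd 0.8) and DL uniformly on
  $[-0.5, 0.95]$ — ranges chosen to resemble the packaged table — and
  then **forces** each compound to the intended side of each threshold,
  so the planted pass count is exact by construction and filter tests
  cannot flake.
* `gen_interaction_edges()` draws per-compound target counts from a
  shifted geometric (heterogeneous degrees, as database fishing
  produces), splits edges over three synthetic sources and duplicates
  30% of them across sources, so merging must actually deduplicate.
* `gen_expression_matrix()` lays a log-normal baseline (log-mean 5,
  log-sd 0.5 by default) and multiplies planted cells by a boost factor;
  at the default boost of 8 planted calls are recovered exactly under
  the fixed seeds used in the suite.
* `gen_two_group_matrix()` uses unit-normal noise with a mean shift of
  `effect_sd` (default 3) planted in the disease group.

All generators are pure functions of their arguments including the seed,
and they restore the caller's RNG state. The distributions are pragmatic
emulations — they make recovery properties provable, but they do not
model probe-level correlation, batch structure, heavy intensity tails or
real herb chemistry. Passing the planted-recovery suite therefore
demonstrates the *machinery* is correct, not that real atlases or GEO
series will behave as cleanly.

## Numerical and degenerate-input choices

* Hypergeometric tails go through `phyper` (log-space internally); the
  suite verifies exact agreement with combinatorial enumeration for all
  universes up to $N = 12$.
* Betweenness normalization returns 0 for graphs with fewer than 3 nodes.
* `estimate_prior()` requires at least 10 genes, excludes zero variances
  from the log-moment fit, errors on all-zero input, and falls back to
  $(d_0 = 4,\ s_0^2 = \text{mean variance})$ with a message if the
  moments are non-finite.
* Parsing is strict TSV with a mandatory header; comma-separated files
  are rejected, not sniffed; parse errors name the row and column.
* Gene symbols are uppercased once at ingest; every later match is exact
  string equality.
* The packaged target table keeps rows verbatim as printed, including
  one obsolete accession (calmodulin under P62158): provenance over
  currency.

## Problem sizes in the shipped tests

The suite runs on: 200 random graphs of at most 8 nodes against the
betweenness oracle; the full hypergeometric sweep to $N = 12$; 1000
random descriptor vectors for Tanimoto properties; 50 synthetic compound
tables for filter properties; a 179-gene x 84-tissue synthetic atlas; and
two-group designs of 200-400 genes at 10 samples per group. These sizes
make the whole suite run in well under a minute while still exercising
every code path; all scale linearly if users wish to rerun the
properties at larger sizes.

## Known limitations

* No live database access: TCMSP/SEA/BindingDB/UniProt/GEO/KEGG exports
  are files the user supplies. Identifier currency is the user's
  responsibility.
* The enrichment replacement does not reproduce any specific web tool's
  term database or clustering, only the statistic; published term counts
  from such tools are database-version-dependent and not comparable.
* The moderated t implements the core statistic only — no intensity
  trend, no robust prior, no log2 auto-transformation heuristics.
* Organ localization is a threshold rule; it deliberately does not test
  tissue specificity statistically.
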