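---
title: "Methods: cross-comparative DEG analysis and diseasome construction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-comparative DEG analysis and diseasome construction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diseasomeR)
```

## The analytical question

Many chronic diseases travel together: a focal disease (say, cardiovascular
disease) co-occurs with candidate risk factors such as hypertension, type 2
diabetes, hypercholesterolemia, obesity and aging. One molecular route to
quantifying those links is cross-comparative transcriptomics: call
differentially expressed genes (DEGs) independently in a case/control cohort
for each condition, then ask how strongly the DEG sets overlap, which shared
genes sit at the centre of the protein–protein interaction (PPI) network,
and which pathways and curated disease–gene sets the shared genes light up.
`diseasomeR` implements that pipeline end to end, together with a synthetic
data generator that plants known structure so every stage can be tested
against ground truth.

## Per-cohort differential expression

Each cohort is a genes × samples matrix with case/control labels.
Preprocessing offers three steps:

* **Probe collapsing** (`collapse_probes()`): one row per gene symbol. The
  default rule keeps, per symbol, the probe with the largest absolute
  difference of case and control means; ties break to the
  lexicographically smallest probe identifier so results are reproducible.
  A `mean` rule (per-sample average) is available.
* **Log2 transformation** (`maybe_log2()`): applied as `log2(x + 1)` when
  the data look like raw intensities. The `auto` policy uses a common
  heuristic for array data: transform only when the 99th percentile exceeds
  50 and no value is negative. Matrices containing negative values are
  taken to be on a log scale already.
* **Z-scoring** (`zscore_rows()`): each gene row is standardised to mean 0,
  sd 1 across *all* samples of the cohort (cases and controls jointly), the
  usual device for making cohorts from different platforms comparable.
  The standard deviation uses the sample (`ddof = 1`) form by default;
  rows with zero variance cannot be standardised and are dropped with a
  warning.

DEGs are called by `call_degs()` with the unpaired Student's t-test (pooled
variance; Welch's form is available as an option) and inclusive thresholds:
a gene is *up* when p ≤ 0.05 and log2 fold change ≥ 1, *down* when p ≤ 0.05
and logFC ≤ −1. The log fold change is the difference of log2-scale group
means (case − control), the standard two-group convention. Both raw and
Benjamini–Hochberg-adjusted p-values are always reported; the selection
criterion defaults to the raw p-value with the adjusted criterion one
argument away.

Two ordering decisions deserve a note. First, the fold change is computed
on the log2 scale *before* Z-scoring: standardising rescales every gene
separately, which would make a fixed logFC threshold unit-dependent,
whereas the t statistic (and hence the p-value) is invariant to per-row
affine transforms — a property the test suite checks directly. Second, the
pipeline uses the plain two-sample t-test rather than moderated
(empirical-Bayes) linear-model statistics; moderation is deliberately out
of scope, so p-values on very small cohorts are noisier than a
limma-style analysis would give.

## The diseasome

For diseases $i$ and $j$ with dysregulated gene sets $G_i$ and $G_j$, the
pipeline computes the shared count and the Jaccard edge-prediction score

$$ n_{ij} = |G_i \cap G_j|, \qquad
   E(i,j) = \frac{|G_i \cap G_j|}{|G_i \cup G_j|}, $$

per direction (up-only, down-only) and combined, because overlap totals are
conventionally reported split by direction. `build_diseasome()` assembles
the bipartite gene–disease graph: each disease node is linked to the genes
it shares with the focal disease, per direction, and every unordered
disease pair sharing at least one gene receives an `n_shared`/`jaccard`
entry. `membership_patterns()` lists genes linked to several diseases at
once — the multi-morbidity candidates the network exists to reveal.

When the focal disease is represented by several cohorts (e.g. two related
conditions standing in for one disease), `combine_focal_datasets()` unions
the up-sets and down-sets separately. A gene called up in one cohort and
down in another is direction-conflicted: it is removed from both sets and
reported, because assigning it either direction would be arbitrary.
Gene symbols are uppercased on both sides of every comparison, since HGNC
symbols are uppercase but annotation files vary.

## PPI hubs

The PPI stage takes a user-supplied undirected edge list (self-loops and
duplicate edges removed; an optional confidence-score column can be
thresholded), restricts it to the shared DEGs, and ranks proteins by
degree. `top_hubs()` returns the top *k* (default 10, the conventional hub
panel size) with deterministic lexicographic tie-breaking; `include_ties`
keeps all proteins tied with the k-th degree. Degree is the only scorer
implemented — it is the metric the ranking interface is built around — and
each node can carry, as a GraphML attribute, the set of risk factors whose
shared-DEG list contains it.

## Enrichment and benchmark validation

`enrich()` is a local over-representation test against any GMT library:
with universe size $N$, term size $K$, query size $n$ and overlap $x$, the
p-value is the hypergeometric tail $P(X \ge x)$. The default background is
the union of the library's genes (the convention of popular enrichment
servers); an explicit measured-gene background can be supplied, in which
case term sets are restricted to it. Significance is flagged at raw
p ≤ 0.05 by default — matching the conventional pathway-selection rule —
with BH-adjusted values always reported; no combined score is computed
because selection is on p only. `validate_against_benchmarks()` runs the
same test against disease–gene benchmark libraries and reports, per target
disease, whether it is testable and significant — the validation step that
checks a DEG list recovers known disease associations.

## The synthetic test bed

`simulate_expression()` draws every value from
$\mathcal{N}(\mu_0, \sigma)$ on the log2 scale ($\mu_0 = 7$,
$\sigma = 0.5$ by default, values typical of log2 microarray intensities)
and shifts planted genes' case samples by ±2 log2 units — an effect size at
the lower end of what the |logFC| ≥ 1 rule is meant to catch reliably at
n = 15 + 15, which makes recovery rates analytic: the fold-change estimate
has standard error $\sigma\sqrt{2/n} \approx 0.18$, so a planted gene
misses the threshold with probability $\Phi(-5.5) \approx 2\times10^{-8}$
and a null gene crosses it essentially never. Gaussian noise on the log
scale matches the t-test's assumptions; what the generator deliberately
does *not* emulate are probe-level artifacts, batch effects, platform
differences, correlated genes or heavy-tailed noise — so passing recovery
tests demonstrate the pipeline's correctness, not robustness to real
microarray pathology. A single root seed derives one substream seed per
cohort, so adding a cohort leaves the others' matrices bit-identical.

`simulate_ppi()` plants hubs by wiring each to exactly its requested
degree among non-hub nodes while capping every non-hub's degree at
one less than the smallest planted hub degree; the requested edge total is
a target that can be curtailed by the cap, and infeasible requests are
rejected up front. `simulate_gmt()` plants one term containing a chosen
fraction of the query plus random filler, with all other terms drawn
uniformly — so the planted term is the only enriched one by construction.

## Problem sizes and numerical choices

The recovery checks in the test suite and the acceptance script use
5 cohorts × 2,000 genes × 15 + 15 samples across 20 simulation seeds for
DEG/overlap recovery, 100-node graphs with 3 planted hubs for hub
recovery, and 200-term libraries over a 1,000-gene universe with a
20-gene query (80 % planted overlap) for enrichment recovery — sizes at
which the analytic error rates above are negligible while a full run stays
in the tens of seconds. Statistical primitives are verified against
independent oracles: the pooled t against `stats::t.test`, BH against a
direct double-loop over the step-up definition, and the hypergeometric
tail against exhaustive enumeration of all draws for universes up to 30.
All threshold comparisons are inclusive; degenerate rows (zero pooled
variance) yield t = 0, p = 1 when the means agree and p = 0 with a warning
when they do not; the Jaccard score of two empty sets is undefined and
returned as `NA` with a warning.

## Limitations

Results at real-data scale depend on database versions (PPI edges, GMT
libraries) and platform annotation, none of which the package fetches:
all external resources are user-supplied files. The pipeline reproduces a
methodology, not any particular study's gene lists. The raw-p selection
rule is liberal by modern standards — the adjusted-p criterion is provided
and recommended when cohorts are well powered — and degree is a
deliberately simple hub statistic; betweenness or MCC hubs would need an
additional scorer.
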