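---
title: "Methods: interconnectivity of small-molecule target networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interconnectivity of small-molecule target networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reprognet)
```

## The question and the statistic

Small molecules (SMs) used for chemical cell reprogramming hit many
protein targets. If those targets acted independently we would expect
them to be scattered across the protein–protein interaction (PPI)
network; if they act cooperatively we expect them to be wired together.
`reprognet` quantifies "wired together" with the **interconnectivity**
of a query set $S$ in an interactome $G$:

$$ f(S) \;=\; \frac{|\mathrm{LCC}(G[S])|}{|S \cap V(G)|} $$

where $G[S]$ is the subgraph induced by $S$ (only edges with both
endpoints in $S$) and LCC its largest connected component, found by
breadth-first search over the induced edges. Two conventions matter and
are fixed deliberately:

* **Denominator = mapped symbols.** Query symbols absent from the
  interactome carry no connectivity information, so the denominator is
  $|S \cap V(G)|$, not the raw query size. Both counts are reported
  (`n_input`, `n_mapped`) so either normalization can be recovered.
* **Degenerate sets are defined, not errors.** A single mapped node is
  a connected component of size 1 ($f = 1$); a query that maps to
  nothing yields a *missing* fraction with a warning, because "no
  information" and "not connected" must not be conflated.

### The interactome and its cleaning rules

Raw interaction records (BioGRID-TAB-like or a compact five-column TSV)
pass through four rules, in order: genetic interactions removed
(physical only), interactions involving another species removed,
self-loops removed, duplicate edges collapsed (edges are unordered
pairs). Each rule's removal count is kept as provenance and the counts
sum exactly to input rows minus surviving edges. Nodes are defined as
endpoints of surviving edges: a protein seen only in removed rows is
not part of the graph. That choice (rather than keeping isolated nodes)
makes the cleaned graph coincide with the support of the null sampler —
every samplable node can in principle connect.

## The resampling null model and z-scores

The null asks: how interconnected would an *arbitrary* node set of the
same size be? For observed size $n$ we draw replicates of $n$ distinct
nodes uniformly without replacement from $V(G)$, compute $f$ for each,
and summarize mean and SD (unbiased, $n-1$ denominator). The z-score is
$(f_{obs} - \bar f_{null}) / s_{null}$, with no continuity correction;
a zero-SD null (e.g. a complete graph) reports a missing z rather than
an infinite one. Sampling is deliberately *not* degree-matched: the
reference hypothesis is plain random node selection, and the
size-stratified expectation curve makes the strong size dependence of
$f$ explicit instead of hiding it in a matching scheme.

Defaults follow the conventional settings of this analysis style:
**100 replicates per point** for the expectation curve (it is a trend
display) and **1000 replicates** for significance testing. The curve
grid starts at 50 nodes because the statistic is extremely variable for
tiny sets. The z-score is scale-invariant, so fractions are kept on
$[0,1]$ internally even where percentages are printed.

Reproducibility is structural, not incidental: every replicate seed is
derived from the master seed and a counter, and every pipeline stage
derives its seed from the master seed and the stage name. Results are
therefore independent of execution order, and adding a stage or a grid
point never perturbs existing random draws.

### Calibration honesty

The null fraction distribution at moderate sizes is discrete and
right-skewed, so $|z| > 1.96$ does not occur at exactly 5%: on a
3000-node preferential-attachment graph with 100-node queries the
exceedance rate is about 0.056, entirely from the right tail. The test
suite asserts the rate in a band ([0.02, 0.10]) rather than at the
normal-theory point value for exactly this reason.

## Degree-distribution topology

`fit_power_law()` is the classic network-viewer regression: ordinary
least squares of $\log_{10} P(k)$ on $\log_{10} k$, where $P(k)$ is the
**raw count** of nodes with degree exactly $k$ (coefficients much
larger than 1 are expected), over all $k \ge 1$ with positive counts.
Degree-0 nodes are excluded (their log is undefined) and noted. No
logarithmic binning, no tail truncation: the full support is fitted and
the `k_range` is reported so the choice is visible. This estimator is
kept because it is the one conventionally reported with such networks;
a discrete maximum-likelihood tail fit (`power_law_ml()`, via igraph's
plfit) is offered as a clearly separate diagnostic, never mixed into
the regression output. The two answer different questions and can
legitimately disagree.

The scale-equivariance property (multiplying all counts by $c$
multiplies the coefficient by $c$ and leaves the exponent fixed) is
exact for OLS and is tested exactly.

## Overlap and enrichment statistics

`fisher_overlap()` always demands an **explicit background universe**
— overlap p-values are meaningless without one, and published
backgrounds (e.g. "all compounds of a database version") are not
reconstructible. Members outside the universe are dropped with a
logged count, mirroring the practice of restricting comparisons to
genes present in both sources. The test is the exact hypergeometric
(one-sided "greater" by default), and the test suite checks it against
exhaustive enumeration of all tables with universes up to 12.

`enrich()` is the generic hypergeometric set-enrichment with
Benjamini–Hochberg adjustment ("Benjamini correction" is read as BH,
the default of the popular enrichment servers, not Benjamini–
Yekutieli). The conventional reporting filter (adjusted p < 0.001,
fold ≥ 2) is a separate view, `enrich_filter()`, so the full table is
never hidden. An EASE-style variant (scoring $k-1$ hits) exists as an
option because enrichment servers use it, but it is off by default and
nothing downstream depends on it — server p-values are bound to
database snapshots and are not reproduction targets.

## Cocktail combinatorics

The ten published reprogramming cocktails and the catalog of their 22
non-redundant SMs ship as plain-text fixtures, with synonyms (`VPA`,
`TSA`, `AM580`, the single-letter shorthands `V`, `C`, `6`, `T`, `F`)
resolved by a case-insensitive canonicalizer that suggests nearest
matches on failure. Frequencies are computed from the compositions, not
copied: the package reports CHIR99021 in **8** of 10 cocktails because
that is what the listed compositions contain, while the accompanying
running text of the source literature says 7 — the discrepancy is
inherent to the source and deliberately left visible.

Category coverage uses one explicit mapping per SM: HDAC/HMT/DNMT/
LSD1/DOT1L inhibitors are epigenetic; GSK3 inhibitors are metabolic
(they switch metabolism toward glycolysis); TGF-β, cAMP, retinoic-acid,
ROCK, MEK and p53 modulators are signaling. One judgment call was
required: **BrdU** is tagged epigenetic *and* signaling. As a thymidine
analog it is incorporated into DNA and perturbs DNA methylation and
chromatin state; without that reading, the BrdU cocktail would have no
epigenetic member, contradicting the observation that every published
cocktail covers all three activity categories. The tag is recorded in
the fixture where it can be audited or changed.

## What the synthetic data emulates — and what it does not

The generators reproduce the *statistical structure* the analysis
relies on:

* `gen_scale_free(n, m, seed)`: preferential-attachment growth —
  heavy-tailed degrees, a hub core, connectedness. Default study size
  n = 3000 with m = 2 (≈ 6000 edges): large enough for stable null
  curves, small enough that a thousand-replicate z-score takes a
  fraction of a second.
* `gen_er(n, p, seed)`: the density-matched random-graph control for
  topology comparisons.
* `gen_planted_target_map()`: chemicals whose targets are drawn, with
  probability `purity`, from a **planted module** — the 100 top-degree
  nodes. Choosing the existing hub core (rather than wiring in an
  artificial clique) leaves the graph and its degree sequence
  untouched, so the same graph serves as its own honest null: purity 1
  produces strong signal, purity 0 produces target sets the null model
  should *not* flag. "Highest total internal degree subset" is
  NP-hard in general; the top-degree rule is the deterministic
  surrogate, and in a preferential-attachment graph it is the densely
  wired core by construction. The module is kept small (100 of 3000
  nodes) so that purity-0 sets, which avoid the module, remain close
  to uniform draws.
* `gen_overlap_universes()`: compound universes with exact overlap
  cardinalities for Fisher tests.

What is **not** emulated: real interactomes are orders of magnitude
larger (tens of thousands of nodes), have study-bias-correlated degree
(well-studied proteins have more edges and more drug annotations),
multi-evidence edges, and identifier noise. Passing tests on synthetic
data therefore validate the *statistical machinery* — calibration,
signal recovery, determinism, exactness of the combinatorics — not any
biological claim about a particular database snapshot. Quantities tied
to specific releases (the 85.8% interconnectivity of the full SM target
set, its z ≈ 9.4, the fitted $221 k^{-1.16}$, database-overlap
p-values) are reproducible only with those releases and are treated as
external reference points, not as package outputs.

### Purity-0 caveat

Purity-0 target sets are drawn from the non-module nodes, i.e. they
*avoid* the 100 hubs, which a uniform null sample would occasionally
include. This induces a mild negative bias of the purity-0 z-scores
(empirically about −0.6 on the default study conditions) — visible,
expected, and well inside the ±1.96 acceptance band.

## Numerical and degenerate-input choices

* Ties in component size are irrelevant: only the maximum size is used.
* `sd = 0` nulls, empty chemical tables, unmapped queries, empty
  cleaning results and an empty curve grid all degrade to warnings with
  well-defined outputs; hard errors are reserved for malformed files
  (with line diagnostics), impossible requests (sample size exceeding
  the graph) and unknown SM names.
* STITCH-style scores are accepted on the native 0–1000 scale or the
  unit scale, declared explicitly, and always stored on $[0,1]$ so the
  medium-stringency threshold 0.4 is literal.
* Symbols are upper-cased and whitespace-trimmed everywhere; synonym
  resolution happens only through the explicit catalog, never by
  heuristics.
* Problem sizes used by the test suite and acceptance script (3000-node
  graphs, 100-seed recovery runs, 200–500-trial calibrations, 10000-
  replicate closed-form checks) are the package's study conditions,
  chosen to make Monte-Carlo bands tight relative to the effects under
  test.

## Known limitations

* No degree-preserving (rewiring) null: z-scores answer "more
  interconnected than a random node set", not "than a random set of
  equally popular proteins". With study-biased real data the second
  question is harder and the first can overstate novelty.
* The log-log regression is a descriptive fit; it is not a hypothesis
  test for scale-freeness, and none is offered.
* Enrichment is flat (no ontology structure, no pathway topology).
* The ortholog map is consumed precomputed; no orthology inference.
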