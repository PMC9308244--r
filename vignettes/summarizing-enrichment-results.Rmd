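---
title: "Summarizing enrichment results by subset coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Summarizing enrichment results by subset coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enrichsum)
```

## The problem

Over-representation analysis of a gene list against a hierarchical
annotation database (GO, Reactome) typically returns hundreds of
significant terms, most of them related by parent–child links. Because an
ancestor term annotates every gene its descendants annotate, a significant
child drags its ancestors toward significance and vice versa, and the
result list repeats the same biology at many levels of detail. The problem
compounds when several enrichment results — different diseases, conditions
or tools — must be compared: the interesting question ("which biology is
shared, which is condition-specific?") is buried under redundant rows.

## The filtering principle

enrichsum reduces a set of ranked enrichment results with a single rule:

> a term is discarded when a more significant term annotates **at least the
> same genes**; the more significant term becomes its *representative*.

Operationally, term $a$ *covers* term $b$ when
$\mathrm{genes}(b) \subseteq \mathrm{genes}(a)$, with set equality counting
as coverage. Gene sets come from a user-supplied GMT file; the method never
sees the query genes or the significance values themselves, only the rank
order of the terms (most significant first) and the GMT. Because coverage
is exact set containment, the output is foreseeable: no similarity
threshold has to be tuned, and a term can only disappear in favour of a
term that demonstrably subsumes its annotation. When a specific term is
*more* significant than its ancestor, both are kept — specific, strong
signal is never sacrificed to a weaker general term.

The rule only bites when the annotation collection is hierarchical
(containment-rich). For flat collections with partially overlapping terms
almost nothing is covered and the filter correctly leaves the input alone;
clustering approaches are the better tool there.

### Collective filtering of several results

With multiple input results the lists are merged first: duplicates are
removed and each term receives the **best (minimum) rank** it has in any
input. Filtering then happens once, on the merged ranking, so the
representatives are common currency across all inputs and per-source
presence can be read off a single table.

### Processing order

The description "start with the top-ranked terms" leaves ties unspecified.
We process terms by best rank ascending, breaking ties by first appearance
when the input lists are scanned position by position in the order the user
supplied them (rank 1 of list 1, rank 1 of list 2, …, rank 2 of list 1, …).
This is deterministic, reproducible, and respects the user's list order;
it is a design choice, not a property of the method. For equal gene sets
the same order decides: the earlier term represents the later one.

The walk assigns each term to the *first* earlier surviving term that
covers it, or makes it a new representative. Comparing only against
survivors loses nothing: if $t \subseteq s$ and $s \subseteq r$ with $r$
surviving, then $t \subseteq r$ by transitivity — the test suite verifies
this against a naive reference that scans all earlier survivors after
precomputing the full pairwise containment matrix. Representation is flat:
a discarded term maps directly to a surviving representative, never to a
chain of discarded terms.

## Parameters

* **`min_term_size`** (genes, default 10). Terms annotating fewer genes
  than this are dropped before filtering (strict `<`, so a term of exactly
  the threshold size survives). Very small terms carry little specific
  information and many other terms annotate the same few genes.
* **`max_representative_size`** (genes, unset by default). When set, a
  term larger than the cap may never *represent* another term. A very
  significant, very general term would otherwise absorb much of the list;
  capping representative size keeps more specific terms visible. By
  default oversized terms are removed from the output entirely (recorded
  in `oversized_ids`): retaining them as self-only representatives would
  defeat the parameter's purpose of surfacing specific terms. Because the
  alternative reading is defensible, `keep_oversized_as_self = TRUE`
  switches to it.
* **`top_n_plot`** (default and maximum 50): number of representatives
  shown in the heatmap and barplot. Selection is the first N groups in
  processing order, i.e. the best merged ranks.

## Reported quantities

For every representative group (the representative plus the terms it
represents) and every input result, reports carry the **best rank over the
group members** present in that source. The best-of-group convention is a
design choice: it reflects the group's collective significance and keeps a
representative visible in a source where only its children were enriched.

The heatmap colours each group/source cell by the **quartile** of that
rank: $Q = \lceil 4r/L \rceil$ for rank $r$ in a source list of length
$L$, clipped to $1..4$; sources containing no group member get a distinct
"absent" colour. In the degenerate single-term list the formula yields Q4
and we keep that value rather than special-casing it. The quartile formula
and colour scheme are this package's own operational definitions.

`size_representation_correlation()` computes Spearman's rank correlation
between the number of genes each representative annotates and the number
of terms it represents. Large general terms cover more gene sets, so a
positive correlation is the expected signature of the filtering rule. With
fewer than three representatives the statistic is refused; with zero
variance in either variable it is undefined and returned as `NA` with a
warning. Ties are handled by the usual asymptotic approximation of
`stats::cor.test`.

## Synthetic data: what it emulates, and what it does not

`generate_ontology()` builds a forest: disjoint root gene sets partitioning
a synthetic universe, each child inheriting a random fraction of its
parent's genes. This reproduces the one structural property the method
relies on — ancestors annotate supersets of descendants — and yields
collections where filtering has real work to do. Defaults (universe 2000
genes, 5 roots, depth 4, branching 3, child fraction 0.5, giving 200 terms
of sizes 400/200/100/50) were chosen once as a realistic desk-scale
stand-in for a GO-slice: deep enough for multi-level redundancy, small
enough that every test runs in seconds.

It does **not** emulate several features of real annotation databases:
multiple parentage (a GO term can have several parents, so real "siblings"
overlap partially; our siblings overlap only through their common
ancestor), term sizes spanning five orders of magnitude, annotation noise,
or terms sharing genes without containment. Passing tests on these
fixtures therefore certify the algorithmic contracts — coverage soundness,
partition, idempotence, oracle equivalence — not the biological usefulness
of any particular filtered list.

`generate_artificial_query()` mirrors the benchmark construction for
enrichable inputs: choose a source term annotating more than 100 genes
(say $n$ genes), take $\lfloor n/2\rfloor$ of its genes and add
$\lceil n/2\rceil$ genes drawn from the rest of the universe. For odd $n$
the annotated half rounds down — the construction only fixes "$n/2$", so
integer semantics are ours. The random half is drawn from the universe
excluding only the genes already chosen, so it may by chance re-hit other
genes of the source term; the tests assert the analytically expected
source-gene fraction under exactly this definition rather than a nominal
one half. A fully random list would rarely be enriched in anything, which
is the point of seeding half of it.

`run_ora()` is a plain hypergeometric over-representation test with the
GMT universe as background (the only coherent background the harness
knows), Bonferroni correction over the number of tested terms, and an
$\alpha$ of 0.05 on adjusted p-values. The upper tail is computed by
`stats::phyper`, which works in log space; the tests pin it against exact
combinatorial summation on every parameter grid up to universe size 60.
Output lists are ordered by raw p with ties broken by term ID, and carry
no significance values — deliberately matching the filter's input
contract, which consumes rank order only.

## Numerical and degenerate-input choices

* Gene and term identifiers are compared as exact strings after trimming
  surrounding whitespace; no case folding. GMT dialects differ, and silent
  case-merging can conflate distinct genes.
* Duplicate genes within one GMT line are collapsed silently (benign
  redundancy); duplicate *term IDs* in a GMT or in one ranked list are
  errors — guessing which entry the user meant would be worse.
* Ranked result files may carry extra tab-separated columns; only the
  first is read. `#` comments and blank lines are skipped.
* Terms present in a result but absent from the GMT cannot be size- or
  coverage-checked; they are set aside with a warning and reported in
  `unannotated_ids` rather than silently dropped.
* An empty survivor set (everything undersized) is legal: reports are
  written with headers only and figures are skipped.
* `write_gmt()` emits genes in lexicographic order so round trips and
  repeated runs are byte-identical.

## Problem sizes in the test suite

The property battery runs the filter against the independent
containment-matrix reference on 100 random collections of 25–200 terms,
checks the hypergeometric tail on all grids with universe ≤ 60, and runs
the end-to-end recovery benchmark (artificial query → ORA → filtering →
source term or a covering ancestor among representatives) on 100 seeded
queries against the 200-term fixture ontology. These sizes keep each
module's check in the seconds range while exercising every code path;
they are the package's chosen desk-scale study conditions.

## Known limitations

* Coverage is exact containment. A child missing a single gene of its
  parent's set (annotation lag, GMT version skew between the enrichment
  run and the GMT given here) breaks coverage and both terms are kept.
  Using the *same* GMT for enrichment and filtering avoids most of this.
* Ranks are the only significance information used; two terms with nearly
  identical p-values are still strictly ordered, and the winner of a
  coverage pair is decided by that order.
* The per-disease and collective published use case this method was
  demonstrated on requires externally deposited inputs; the package
  reproduces it when those files are supplied locally but does not ship
  them.
* REVIGO-style semantic-similarity filtering and live database queries
  are out of scope by design; this package only consumes files.
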