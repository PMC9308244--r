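# enrichsum

Collective filtering and comparison of functional enrichment results.

## The problem

Enrichment analyses against hierarchical annotation databases (GO,
Reactome) return long, redundant term lists: an ancestor term annotates
every gene its descendants annotate, so parents and children become
significant together and the same biology is reported at many levels of
detail. Comparing several such results — different diseases, conditions,
or tools run on the same gene list — makes this worse. enrichsum is for
anyone holding one or more rank-ordered enrichment results plus the GMT
annotation file they were computed against, who wants a short,
study-specific list of representative terms and a term-by-source
comparison view.

## The method

The filter applies one rule. Let genes(t) be the gene set a term t
annotates in the GMT. Walking terms from most to least significant, a
term t is **discarded** when an earlier surviving term r **covers** it,

    genes(t) ⊆ genes(r),

and r becomes t's *representative* (set equality counts as coverage; the
better-ranked term wins). Terms survive otherwise. With several input
results, the lists are first merged: duplicates removed, each term keeping
the **best rank** it has in any input, so all results are filtered
collectively and share one set of representatives.

Two optional size parameters: `min_term_size` (default 10) removes tiny
terms before filtering; `max_representative_size` (off by default)
prevents terms above the cap from representing others, keeping more
specific terms in the output.

There are no similarity thresholds. Because coverage is exact set
containment, the filter only works as intended on hierarchy-structured
collections — exactly the databases whose redundancy it targets.

## Worked example

The package ships a synthetic-data module that builds a GO-like hierarchy
(ancestor gene sets are supersets of descendant gene sets) and
enrichable inputs, so the whole pipeline can be exercised without any
download:

```r
library(enrichsum)

onto <- generate_ontology(seed = 1)      # 200 terms over 2000 genes
write_gmt(onto, "annotations.gmt")
for (i in 1:4) {                         # four ranked enrichment results
  q <- generate_artificial_query(onto, seed = 10 + i)
  r <- run_ora(q$genes, onto, alias = paste0("cond", i))
  writeLines(r$term_ids, sprintf("cond%d.txt", i))
}

res <- run_enrichsum("annotations.gmt", sprintf("cond%d.txt", 1:4),
                     sprintf("cond%d", 1:4), "out", top_n_plot = 20)
#> read GMT: 200 terms, 2000 genes
#> read 'cond1': 37 terms
#> read 'cond2': 40 terms
#> read 'cond3': 37 terms
#> read 'cond4': 36 terms
#> merged: 77 unique terms
#> undersized (< 10 genes): 0; unannotated: 0; remaining: 77
#> representative terms: 2
```

The 150 rows of the four input results collapse to 77 unique terms and
then to 2 representatives — the two root terms the artificial queries
were seeded under, each covering every significant descendant. The output
folder contains the five artifacts: `enrichsum-Summary.tsv` (one row per
representative), `enrichsum-Detailed.tsv` (plus one row per represented
term), a clickable `enrichsum.html`, and a rank-quartile heatmap and
represented-count barplot (PNG and SVG):

```
representative_id  description    term_size  n_represented  rank_cond1  rank_cond2  rank_cond3  rank_cond4
T0002              level 1; root  400        39             1           1                       1
T0003              level 1; root  400        36                                     1
```

`term_size` is the number of genes the representative annotates,
`n_represented` how many discarded terms it stands for, and the
`rank_*` columns give the group's best rank in each input result (empty =
no group member significant in that source). Capping representative size
excludes the two 400-gene roots and surfaces the next level instead:

```r
res <- run_enrichsum("annotations.gmt", sprintf("cond%d.txt", 1:4),
                     sprintf("cond%d", 1:4), "out2",
                     max_representative_size = 250, top_n_plot = 20)
#> ...
#> representative terms: 6; oversized removed: 2
```

A command-line front end with the same options lives at
`inst/cli/enrichsum.R`:

```sh
Rscript inst/cli/enrichsum.R --gmt annotations.gmt \
  --files cond1.txt,cond2.txt,cond3.txt,cond4.txt \
  --fileAliases c1,c2,c3,c4 --outputFolder out --minTermSize 10 \
  --numberOfTermsToPlot 20
Rscript inst/cli/enrichsum.R synth --seed 1 --outputFolder fixtures
```

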