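# kwtrends

Temporal and network trend analysis of publication keywords ("co-word"
trend analysis). Given article metadata — a publication year and a list
of author keywords per article — the package answers two questions about
a literature: **when did its research topics change**, and **which topics
moved together over time**.

It was built around the analysis design used for the OASIS
Korean-medicine bibliography (29,876 articles, 1963–2018): from the
keyword lists an annual keyword-frequency matrix is constructed, topic
drift is measured year over year, the timeline is segmented into
research phases, and a keyword network clustered with the Markov Cluster
algorithm reveals groups of keywords with a shared temporal fate. The
original corpus is not redistributable, so the package ships a
synthetic-corpus generator with planted structure that lets every stage
be validated against a known ground truth at the study's real data
volume.

## The method

Everything derives from the annual frequency matrix `F`, where `F[k, y]`
is the number of articles published in year `y` containing keyword `k`
(keywords are normalized — case folded, with everything but Latin
letters, digits and Greek letters removed — merged through a curated
synonym map, deduplicated within articles, and filtered to a minimum
total frequency, 10 by default). Similarity between two frequency lists
is the **weighted Jaccard similarity**

```
J(S, T) = Σ_k min(S_k, T_k) / Σ_k max(S_k, T_k)
```

which is 1 for identical non-zero lists and 0 for disjoint ones.

* **Temporal analysis** applies `J` to consecutive *columns* of `F`; a
  new phase begins where the similarity starts to rise after a sharp
  drop (`segment_phases()`, parameterized; fixed-width bins and the
  six-phase reference preset `oasis_phases()` are also available).
* **Network analysis** applies `J` to *rows* of `F`: nodes are keywords
  with frequency ≥ 100, edges join pairs with row similarity ≥ 0.57, and
  the network is partitioned by a from-scratch **MCL** implementation
  (expansion 2, inflation 2.0, pruning 0.02 — the reference
  parameters).

See the methods vignette (`vignettes/kwtrends-methods.Rmd`) for the
assumptions, parameter meanings and design decisions.

## Worked example

Generate the default synthetic corpus (29,876 articles, 1963–2018, four
planted keyword groups plus a terminology rename in 2012) and run the
pipeline with the reference parameters:

```r
library(kwtrends)

gen <- generate_corpus(corpus_config(), seed = 1)
m   <- build_annual_matrix(gen$articles, gen$synonyms, min_freq = 10)
m
#> Annual keyword-frequency matrix
#>   keywords : 42 (min total frequency 10)
#>   years    : 1963-2018 (56 columns)
#>   articles : 29876

segment_phases(similarity_series(m))
#>   phase start  end
#> 1     1  1963 1978
#> 2     2  1979 1986
#> 3     3  1987 1994
#> 4     4  1995 2001
#> 5     5  2002 2012
#> 6     6  2013 2018

g  <- build_cotrend_network(m, min_freq = 100, min_sim = 0.57)
cl <- mcl_cluster(g, mcl_params())
cl
#> Clustering with 5 cluster(s) over 42 node(s)
#>    1 (n=11): easternmedicine, stable01, stable02, stable03, ...
#>    2 (n=10): declining01, declining02, declining03, ...
#>    3 (n=10): emerging01, emerging02, emerging03, ...
#>    4 (n=10): pulse01, pulse02, pulse03, ...
#>    5 (n=1): nationalmedicine

evaluate_recovery(gen$truth$groups[igraph::V(g)$name], cl)
#> [1] 0.964
```

Reading the output: the segmentation recovers the six planted
article-volume regimes; MCL recovers the four planted co-trend groups
exactly; the pre-rename label (`easternmedicine`) clusters with the
stable group it belongs to, while the post-rename label
(`nationalmedicine`) — which only exists from 2013 — resembles nothing
else strongly enough and comes out a singleton, exactly how a freshly
renamed high-volume keyword behaves; the adjusted Rand index against the
planted groups is 0.964.

`run_pipeline(pipeline_config(corpus = "corpus.csv", ...))` performs the
same steps from files on disk and writes a reproducible artifact bundle
(matrix TSV, similarity series, phase table, GraphML/GEXF network,
cluster table, report, manifest with checksums).

The numbered scripts under `analysis/` run this same study end to end
(`01_simulate` → `05_recovery`), writing tables under `results/` and
regenerable bulk data under `scratch/`.

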