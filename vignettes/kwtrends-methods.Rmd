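---
title: "Co-word trend analysis with kwtrends: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-word trend analysis with kwtrends: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kwtrends)
```

## The analysis in one paragraph

Given article metadata — a publication year and a list of author keywords
per article — the pipeline asks two questions about a literature: *when*
did its research topics change, and *which topics moved together*? Both
are answered from a single object, the annual keyword-frequency matrix
$F$, whose entry $F_{k,y}$ is the number of articles published in year $y$
that contain keyword $k$. Comparing consecutive *columns* of $F$ gives a
year-over-year similarity series whose troughs mark shifts in the topic
mix; comparing *rows* of $F$ gives a keyword-by-keyword similarity that
defines a co-trend network, which a Markov Cluster (MCL) run partitions
into groups of keywords with a shared temporal fate. The motivating
application is the OASIS Korean-medicine bibliography (29,876 articles,
1963–2018), whose corpus is not redistributable; the package therefore
ships a synthetic-corpus generator with planted structure so that every
stage can be validated against a known ground truth.

## Keyword normalization and synonym merging

Raw keyword strings are noisy: `"Anti-Inflammation"`, `"antiinflammation"`
and `"anti inflammation"` are one concept. `normalize_keyword()` applies
Unicode NFC composition, case folding, and then removes every character
that is not a lowercase Latin letter, a decimal digit, or a Greek letter
(`TNF-α` → `tnfα`). Two consequences are worth stating. First, the rule is
idempotent, so normalized tokens are a fixed point and can be stored and
re-processed safely. Second, all other scripts are removed entirely — the
rule targets corpora whose keywords are romanized; a token written only in
Hangul or Han characters normalizes to the empty string and is dropped
from that article's list.

True synonyms (`aqua acupuncture` vs `pharmacopuncture`) cannot be
resolved mechanically; deciding that two spellings denote one concept is a
curation task. The package therefore takes synonym merges as a *data
file* (variant → canonical TSV). `load_synonym_map()` collapses transitive
chains to direct mappings, rejects a variant mapped to two different
canonicals, and rejects cycles, so that applying the map is a single
deterministic lookup.

Counting is article-level: a keyword's frequency is the number of
*articles* containing it, so several raw spellings of one concept inside
one article contribute a single count. This makes the merged count of a
concept at least the largest of its variants' counts and at most their
sum, with equality exactly when no article carried two variants.

## The weighted Jaccard similarity

Both the temporal and the network analysis use one statistic. For
equal-length non-negative frequency lists $S$ and $T$,

$$ J(S, T) \;=\; \frac{\sum_k \min(S_k, T_k)}{\sum_k \max(S_k, T_k)} . $$

$J$ is 1 for identical non-zero lists, 0 for lists with disjoint support,
symmetric, scale invariant ($J(cS, cT) = J(S, T)$ for $c > 0$), and
$1 - J$ is a metric. Because the inputs are integer counts, the two sums
are exact and the result incurs a single floating-point rounding.

One boundary case needs a convention: two all-zero lists. The package
returns $J(\mathbf{0}, \mathbf{0}) = 0$ with a warning. The sparse early
decades of a long-running bibliography contain year pairs in which no
kept keyword occurs at all; treating such pairs as "perfectly similar"
would fuse empty years with each other and distort the first phase
boundary, whereas treating them as dissimilar keeps the early era visibly
unstable. The price is that $J(S, S) = 1$ holds only for non-zero $S$,
which is documented on the function.

## Phase segmentation

`similarity_series()` evaluates $J$ between each year's column and the
previous year's. Segmenting that series into chronological phases is, in
the underlying methodology, an expert judgment — a year belongs to a new
phase when the similarity *starts to rise again after a sharp drop*.
Because no single numeric rule is canonical, `segment_phases()` makes the
judgment explicit and parameterized, and two alternative modes are
first-class:

* **Trough rule** (default): a boundary is placed before year $t$ when
  $\mathrm{sim}(t) - \mathrm{sim}(t-1) \le -\delta$ and
  $\mathrm{sim}(t+1) > \mathrm{sim}(t)$. The leading sparse era — years
  with similarity at or below $\varepsilon$ before the first run of $L$
  consecutive years above $\varepsilon$ — forms the first phase.
  Candidate phases shorter than $L$ years are merged into their
  predecessor. Defaults are $\delta = 0.1$, $\varepsilon = 0$, $L = 3$:
  $\delta$ is a tenth of the similarity scale, and $L = 3$ merges
  back-to-back short dips of the kind a judgment call would decline to
  split into phases of their own.
* **Fixed-width bins** (5- or 10-year periods) via `method = "fixed"`.
* **Externally supplied boundaries**: the six-phase reference split of
  the OASIS study period (1963–1978, 1979–1986, 1987–1994, 1995–2001,
  2002–2012, 2013–2018) ships as `oasis_phases()` and is the faithful way
  to reproduce published phase tables.

Raising $\delta$ can only remove candidate boundaries, so the number of
phases is non-increasing in $\delta$; the suite checks this and the
partition property on fuzzed series.

`phase_aggregate()` then sums the matrix and the per-year article counts
over each phase; totals are conserved by construction, which is also the
package's cross-check on the published reference tables it ships (each
keyword's six phase counts must sum to its total frequency, and the phase
article totals to the corpus size).

## The co-trend network

`build_cotrend_network()` keeps keywords with total frequency at least
`min_freq` (reference value 100) and joins two keywords when the weighted
Jaccard of their annual frequency *rows* is at least `min_sim` (reference
value 0.57), both bounds closed. The edge weight is the similarity
itself. Note what an edge means: the two keywords' annual count profiles
track each other — shared temporal fate, not co-occurrence within
articles. Raw annual rows are compared, without smoothing.

Qualifying nodes with no qualifying edge are kept as isolates. This is
deliberate: the highest-volume keywords of a corpus can be so much larger
than everything else that no other row reaches the similarity threshold,
and they should appear as singleton clusters rather than silently vanish.

Pairwise similarities are computed exactly without a pair loop: for
non-negative rows, $\sum_k \min = (r_i + r_j - d_{ij})/2$ and
$\sum_k \max = (r_i + r_j + d_{ij})/2$, where $r_i$ are row sums and
$d_{ij}$ the Manhattan distance, so one `dist()` call yields all pairs.
At the intended scale (up to a few thousand keywords, decades of years)
dense $O(k^2)$ computation is trivial and no approximate indexing is
warranted.

Exports are GraphML (via igraph), GEXF 1.2 (written directly; igraph has
no GEXF writer) with the node `frequency` attribute declared and edge
weights on `weight`, and a node-annotated edge-list TSV whose `#node`
comment lines let isolated nodes survive a round trip. All three re-import
with node set, edge set and weights (to at least six decimals) intact.

## Markov Cluster algorithm

`mcl_cluster()` is a full, self-contained MCL implementation on dense
matrices. The column-stochastic transition matrix is built from the
weighted adjacency matrix with self-loops added (policy `"one"`: weight
1.0 on every node — the classic default; `"max"` and `"none"` are
available because plugin implementations differ and the reference run's
internals are not documented). Each iteration applies:

1. **Expansion**: $M \leftarrow M^e$ (reference $e = 2$);
2. **Inflation**: entrywise power $r$ (reference $r = 2.0$), column
   renormalization;
3. **Pruning**: entries below the threshold (reference $0.02$) are
   zeroed, columns renormalized — pruning *after* inflation, the common
   formulation.

Iteration stops when the largest entry change between consecutive
iterations falls below `convergence_tol` ($10^{-6}$ by default, cap 100
iterations). A column that loses all mass to pruning is a hard error
naming the column, rather than a silent renormalization of noise.

Clusters are read off the limit: attractors are nodes with positive
diagonal mass; attractors sharing support in any column are merged into
one attractor system (union–find); every node joins the system of the
attractor with the largest value in its column, ties broken toward the
lexicographically smallest attractor name. Node order is fixed
lexicographically throughout, so the clustering is deterministic and
equivariant under vertex permutation; cluster labels are ordered by size,
then by smallest member.

The test suite verifies, on fuzzed random graphs, that the output is
always an exact partition, that nodes in different graph components are
never co-clustered, and that the limit stays column-stochastic to
$10^{-9}$; on a fixed set of motif and random graphs of at most six
nodes it checks exact agreement with an independently coded dense oracle
that iterates the row-stochastic transpose and reads components off the
limit's support — a different reading of the same limit, which must give
the same partition when the run has converged.

## The synthetic-corpus generator

`generate_corpus()` exists because the motivating corpus cannot ship.
Its default configuration reproduces the study conditions: 56 years
(1963–2018); per-year article counts equal to the six reference per-phase
totals (643, 498, 1889, 5758, 15921, 5167 — 29,876 articles in total)
spread uniformly within each phase; four keyword groups of ten concepts
each with distinct temporal profiles — constant (*stable*), logistic ramp
with onset 2010 (*emerging*, the late-arriving topics), falling logistic
with midpoint 1985 (*declining*, the early-era methods), Gaussian pulse
centred on 1996 with scale 3.5 years (*pulse*, a mid-period methods
fashion); 3–8 keywords per article drawn without replacement; a 10%
synonym-variant rate; and one rename event in 2012 (the year of the real
"oriental medicine" → "korean medicine" renaming) in which a concept's
emitted label switches, so the old label's counts collapse while the
new label's rise.

Two design points. First, each concept's probability mass is split
between its canonical and its variant spelling, and sampling without
replacement operates on *spellings* — so one article can legitimately
contain two spellings of the same concept, which is precisely the case
the article-level deduplication path must handle. Second, the group
profiles were placed by analysis before any test was run: with the ramped
article volume, the expected cross-group row similarity is approximately
$\sum_t v_t \min(w_a(t), w_b(t)) / \sum_t v_t \max(w_a(t), w_b(t))$ over
normalized year weights $v_t$, which for these profiles lies between
about 0.03 (stable vs declining) and 0.30 (stable vs pulse) — well below
the 0.57 edge threshold — while within-group similarity at these count
magnitudes is about 0.9. The recovery benchmark (five seeds, adjusted
Rand index against the planted groups) is therefore expected to succeed
by design, and measures regressions in the pipeline rather than luck.
In practice the renamed concept's *new* label sits just below the edge
threshold against every group and comes out as a singleton cluster —
mirroring how a freshly renamed high-volume keyword behaves in the real
network — costing the ARI a few points (≈ 0.96 rather than 1.0).

What the generator does *not* emulate: keyword-list length correlated
with journal or era, within-article topical coherence (keywords are drawn
independently given the year), drift in spelling conventions over time,
and any text beyond the keyword list. Passing recovery tests therefore
show that the pipeline recovers planted temporal co-trends under
realistic volumes and noise — not that it resolves the semantic
ambiguity of real author keywords.

`evaluate_recovery()` implements the adjusted Rand index from the
contingency-table closed form; the suite cross-checks it against an
independent implementation and on a hand-computed example (ARI
$= 2/17$ for the partitions $\{abc|def\}$ vs $\{ab|cde|f\}$).

## Numerical and degenerate-input choices

* Similarity sums are computed before the single division; inputs are
  validated (equal length, non-negative, no `NA`).
* `segment_phases()` on a degenerate series yields one phase; a
  single-year matrix is an error for `similarity_series()`.
* The annual matrix orders keywords by descending total frequency with
  lexicographic tie-break, making serialized matrices byte-reproducible;
  `run_pipeline()` writes to a staging directory and moves the bundle
  into place only on success, and its manifest records parameters and
  md5 checksums, so identical inputs give byte-identical bundles.
* All generator randomness flows through one explicit seed
  (`withr::with_seed`), leaving the caller's RNG state untouched.

## Problem sizes in the shipped checks

The test suite and the acceptance script run the full default-scale
generator (29,876 articles per seed, five seeds) for the recovery
benchmark — about two seconds per seed — plus 10,000 random triples for
the similarity identities and 1,000 random graphs of up to 30 nodes for
the MCL property checks. These sizes make the whole suite complete in
well under a minute on one CPU while exercising every code path at the
study's real data volume.

## Known limitations

* The trough heuristic is a formalization of a judgment call; on real
  series it will not always reproduce an expert's segmentation (the
  reference six-phase split is available as a preset for that reason).
* The published full-corpus outputs (the 70-node/245-edge network, its
  13-cluster partition, the full similarity curve, and the 1305-keyword
  filter count) require the OASIS corpus or its supplementary keyword
  list, neither of which is redistributable here; the package carries
  the corresponding parameters as presets and validates the pipeline on
  synthetic ground truth instead.
* MCL is run dense; beyond roughly $10^4$ nodes a sparse implementation
  would be needed, which is outside this package's intended scale.
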