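---
title: "Methods: from validated miRNA targets to multi-layer pharmacogenomic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from validated miRNA targets to multi-layer pharmacogenomic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirmultinet)
```

## The analysis in one paragraph

A single microRNA can repress dozens to hundreds of messenger RNAs, so a
panel of disease-associated miRNAs induces a gene set — the validated
target genes (VTGs) — that summarizes the regulatory layer of the disease.
`mirmultinet` implements the full desk-scale analysis around that idea:
interaction records are filtered to those supported by strong functional
assays; the surviving target set is tested for over-represented
disease-ontology terms with a hypergeometric test under Bonferroni
control; the enriched terms are grouped by Wang graph-based semantic
similarity and hierarchical clustering; and each term cluster becomes a
multi-layer network in which the cluster's genes are wired to the miRNAs
that target them, the drugs that act on them and the SNPs that sit in
them, with degree statistics and top-k rankings summarizing each network.

## Evidence filtering

Target databases attach free-text evidence strings to each miRNA–gene
record. We treat an interaction as *validated* when at least one string
names a strong functional assay family: reporter-gene assays
(luciferase), immunoblot/Western blot, or real-time quantitative PCR.
Matching is a case-insensitive substring test after stripping
non-alphanumeric separators from both the string and the keyword, so
"qRT-PCR", "RT qPCR" and "Real-time PCR" all land on the same keywords.
The default keyword set is
`luciferase, reporter, western, immunoblot, qpcr, qrt-pcr, real-time`,
configurable via `evidence_keywords()`. One passing string suffices
(`mode = "any"`); the stricter `mode = "all"` is available because
database vocabularies differ in how they bundle assays into one record,
but it is not the default — evidence fields typically enumerate
alternative assay classes, not a required conjunction. Filtering then
deduplicates to unique (miRNA, gene) pairs ordered lexicographically, so
the pair set is deterministic and idempotent under re-filtering.

## Over-representation analysis

For a universe of $N$ genes, a term annotated with $M$ of them, and a
query of $n$ genes overlapping the term in $k$, the enrichment p-value is
the hypergeometric upper tail

$$p = P(X \ge k) = \sum_{i=k}^{\min(M,n)}
\frac{\binom{M}{i}\binom{N-M}{n-i}}{\binom{N}{n}},$$

evaluated with `stats::phyper`. Design choices, each a flag:

* **Universe** — all genes annotated to at least one term
  (`universe = "annotated"`), the common ORA convention; a custom universe
  can be supplied. Query genes outside the universe are dropped with a
  message, and an empty effective query is an explicit error rather than
  an empty table.
* **Propagation** — a gene annotated to a term counts for all of that
  term's ancestors (true-path rule), default on; `propagate = FALSE`
  restores flat gene-set testing, which is also how pathway-style
  (single-root) collections are handled — same code path, flat DAG.
* **Term-size bounds** — tested terms must have $M$ within
  `term_filter = c(5, 500)` by default, which suppresses degenerate
  one-gene terms; pass `c(1, Inf)` to disable (the package's own tiny
  fixtures do).
* **Multiplicity** — Bonferroni, multiplying by the number of terms
  actually tested ($k \ge 1$ and size bounds satisfied); `adjust_over =
  "all"` counts every annotated term instead. Bonferroni is deliberately
  the only offered procedure: the downstream interpretation (a small set
  of strongly enriched disease terms) favours family-wise control, and
  the gene ratio $k/n$ reported alongside is the effect-size axis of the
  dot-plot export.

## Wang similarity and term clustering

Enriched disease terms are often near-synonyms. To group them we use the
graph-based semantic similarity of Wang and colleagues: for a term $A$,
every term $t$ in $DAG_A$ ($A$ plus its ancestors) receives an S-value

$$S_A(A) = 1, \qquad
S_A(t) = \max_{c \,\in\, \mathrm{children}(t) \cap DAG_A} w_e \cdot S_A(c),$$

where $w_e$ is the semantic contribution factor of the edge relation. The
similarity of two terms is

$$\mathrm{sim}(A,B) = \frac{\sum_{t \in DAG_A \cap DAG_B}
\left(S_A(t) + S_B(t)\right)}{SV(A) + SV(B)},
\qquad SV(X) = \sum_{t \in DAG_X} S_X(t).$$

We use the conventional contribution factors `is_a = 0.8`,
`part_of = 0.6`, and 0.7 for any other relation; all three are
configurable on the ontology object, and weights are required to be
strictly inside $(0,1)$ so S-values strictly decrease along ancestor
chains. Terms are clustered on the distance $1 - \mathrm{sim}$ with
agglomerative clustering (`stats::hclust`); average linkage (UPGMA) is
the default because it is the common default of the heatmap tooling this
replaces, with complete and single linkage available. The dendrogram is
cut so that merges above `cut_height = 0.7` are broken. That default is
calibrated on the package's block fixture — groups of terms sharing a
depth-3 ancestor chain have within-block similarity about 0.70 and
between-block similarity about 0.12, so a 0.7 distance cut separates the
blocks cleanly — and it is a configuration knob, not an empirical claim
about any particular ontology. Cluster labels are re-derived from the raw
cut by ordering clusters by size (descending) and then by smallest member
term id, and the term set is canonically sorted before clustering, which
makes the labelling invariant to input order. Only clusters with at least
two terms are reported by default (`report_clusters(min_size = 2)`);
singletons ride along as an attribute.

## Multi-layer networks and degree statistics

Each reported cluster yields a network over four node types: the
cluster's genes (union of enrichment hit genes across the cluster's
terms — per-term networks are available by passing a single term's hits),
plus the miRNAs, drugs and SNPs linked to those genes. Edges are typed
(`mirna_gene`, `drug_gene`, `snp_gene`), always point into a gene, and
SNPs are distinct square nodes rather than gene attributes, mirroring the
Cytoscape styling conventions the GraphML export carries (gene = circle,
miRNA = diamond, SNP = square, drug = triangle). Cluster genes with no
incident edge are kept but flagged `isolated`, so node counts stay
auditable against the enrichment output.

Degree statistics summarize only the miRNA–gene layer: the mean number of
miRNA partners per gene, and the fractions of genes with fewer than five
(strict) and more than ten (strict) partners; genes with five to ten
partners fall in neither bucket. Means are rounded half away from zero to
one decimal and percentages to two decimals — half-away rounding is what
turns 17/160 = 10.625% into 10.63, which banker's rounding would not.
Rankings count distinct target genes per miRNA (ties broken
lexicographically) and distinct drugs per miRNA-targeted gene.

## The synthetic benchmark

Because the interaction databases behind a real analysis are living
resources, the package ships a generator that emits all five input table
shapes with known ground truth, so every stage is testable offline:

* an ontology as a complete `is_a` tree (default depth 3, branching 3:
  40 terms, 27 leaves) plus a few `part_of` cross-links from deeper to
  strictly shallower levels — a DAG, not a tree — with 500 genes assigned
  uniformly to leaves;
* a panel of 30 miRNAs, of which 3 are *hubs*: each hub targets 80% of
  one planted leaf term's genes, on top of background edges drawn per
  (miRNA, gene) at probability 0.01. Thirty miRNAs keeps the background
  coverage of the universe near 40%, which leaves the planted terms
  clearly over-represented in the pooled target set; much larger panels
  blanket the universe and wash the signal out, which would defeat the
  benchmark's purpose;
* evidence strings drawn from a fixed vocabulary of passing and failing
  assay descriptions (pass probability 0.9), so the filter is exercised
  in both directions;
* drugs concentrated on a few genes by a truncated power law
  (exponent 1.5) and SNPs with synthetic rs-numbers and 1-based
  coordinates.

One integer seed drives the whole bundle; identical configurations yield
byte-identical files, and the emitted truth record (planted terms, hub
miRNAs, row counts) is re-countable from the tables. A separate fixture,
`simulate_similarity_blocks()`, plants block structure for the clustering
stage as described above. What the generator does **not** emulate:
real database accession semantics, correlated evidence quality, genome
positions that exist, or the heavy-tailed target-count distributions of
real miRNAs beyond the hub/background split. Passing recovery tests
therefore demonstrate that the machinery is correct and calibrated on
clean planted signal, not that any specific biological dataset will
reproduce.

Benchmark scale was chosen so the whole recovery sweep (50 seeds of the
default configuration) runs in well under a minute: ORA on 500 genes and
40 terms is effectively instant, and the exhaustive hypergeometric check
against a draw-enumeration oracle is limited to universes of size 12,
where all $\binom{N}{n}$ draws are enumerable.

## Numerical and degenerate-input policy

* Hypergeometric tails come from `stats::phyper` (log-space internals);
  `k = 0` returns exactly 1, and parameter-bound violations are errors,
  not `NA`s.
* A single-term similarity matrix is the 1×1 identity; clustering one
  term returns one cluster without consulting `hclust`.
* `cut_height = 0` separates all distinct terms; distance-0 term pairs
  merge at any positive cut.
* Empty interaction files read as empty record sequences; an
  all-filtered table aborts the pipeline at the enrichment stage with a
  named stage error.
* Ontology loading verifies acyclicity (reporting a witness cycle) and
  rejects dangling parents and out-of-range relation weights.
* Generators restore the caller's RNG state; all randomness flows from
  the configuration seed.

## Known limitations

Information-content similarity measures (Resnik, Lin) are out of scope,
as are GSEA-style ranked tests, FDR procedures other than Bonferroni,
network layout/centrality beyond degree, and any live database querying —
inputs are files with the documented shapes. The OBO reader is
deliberately minimal ([Term] stanzas with `id`, `name`, `is_a`,
`relationship`, obsolete skipping); richer OBO features (intersections,
xrefs) are ignored.
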