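---
title: "Methods: multi-list GO enrichment and semantic-similarity clustering"
author: "goclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-list GO enrichment and semantic-similarity clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goclust)
```

`goclust` implements a functional-mining workflow for studies with several
interest gene lists: topology-aware GO over-representation tests per list, a
merged exploratory table, semantic similarity between the enriched terms, and
hierarchical organisation of terms and of term clusters. This vignette is the
package's account of the underlying methods: what is computed, under which
assumptions, which knobs matter, and where the design was genuinely open.

## The ontology as a graph

GO is treated as a directed acyclic graph per namespace (BP/MF/CC): terms are
nodes, `is_a` and `part_of` relations are typed child-to-parent edges. The
OBO reader interprets only the tags it needs (`id`, `name`, `namespace`,
`is_a`, `relationship: part_of`, `is_obsolete`, `alt_id`) and validates
structure hard: a cycle or an edge to an undeclared term is an error, while
unsupported relation types (e.g. `regulates`) and rare cross-namespace edges
are dropped with a warning. Obsolete terms stay in the term map — so stale
annotation files can be diagnosed — but carry no edges. Alternative ids
resolve transparently to their primary term.

All propagation, similarity and ancestor logic follows `is_a` and `part_of`
by default. The relation set is configurable; these two are the relations the
Wang measure canonically weights, and restricting to them keeps annotation
propagation, the enrichment graph and the similarity graph consistent with
one another.

Term *levels* are longest-path distances from the root (root = 0), not
shortest-path depths. This choice is load-bearing: processing terms in
decreasing level guarantees every child is handled before any of its parents
in the elim sweep, which shortest-path depth does not.

## Annotations and the true-path rule

GAF 2.x rows are filtered by aspect (namespace), optional evidence codes, and
the `NOT` qualifier (negative annotations are discarded); the gene key is the
DB object id (column 2), taken verbatim — identifier mapping across databases
is out of scope, users supply files keyed the way they want to analyse them.
By default all evidence codes are kept, computational and experimental alike;
restricting to experimental codes is a one-argument change.

A gene annotated to a term is implicitly annotated to all its ancestors
(true-path rule); `propagate()` materialises this closure once and caches it.
Everything downstream — gene counts per term, information content, the
enrichment tests — uses propagated annotations.

One decision needed making because it is genuinely underdetermined: whether
background genes *without any annotation* count toward the universe size `N`.
Here they do not. A gene with no GO term can never contribute to any term's
count, so including it would only dilute every test by a constant factor
unrelated to GO; `N` is therefore the number of *annotated* background genes,
and the run log records that number (e.g. "2000 background genes are
annotated with at least one biological_process term") for traceability.

## Over-representation tests

For each term with `K >= 1` annotated genes in the universe, the one-sided
Fisher p-value is the hypergeometric upper tail

$$p = \sum_{k=x}^{\min(n,K)} \frac{\binom{K}{k}\binom{N-K}{n-k}}{\binom{N}{n}},$$

computed as a log-space sum of `lchoose` terms (a log-sum-exp), so very small
p-values keep full relative precision. `x = 0` returns exactly 1. The test
suite pins this implementation to an exhaustive enumeration oracle for every
valid table with `N <= 30`.

Two algorithms are exposed:

* **classic** — every term tested independently.
* **elim** — terms processed in decreasing level (ties by ascending id, so
  runs are bit-reproducible). Each term is tested on its annotated genes
  *minus the genes already eliminated at that term*; when the resulting p
  falls below `alpha` (default 0.01), all genes annotated to the term are
  marked eliminated at each of its ancestors. Elimination bookkeeping is
  per-ancestor: a term's test removes exactly the genes eliminated *at* that
  term, not a global pool. With `alpha` small enough to admit no significant
  node, elim equals classic everywhere — a tested identity.

Reported per-term counts (`x/K`, the "gene frequency", and the significant
gene ids) are the unreduced values in both algorithms, following the usual
enrichment-table convention; only the elim p-value reflects elimination. A
term whose genes are entirely eliminated is reported with p = 1 (no evidence
left) rather than dropped, keeping the table's term set independent of
`alpha`.

`merge_enrich_terms()` retains the union over lists of sub-threshold terms
(default threshold 0.01, independent of elim's `alpha`) and reports every
retained term's p-value in *every* list, so a term significant in one list
shows its (possibly unremarkable) behaviour in the others. P-values are
unadjusted for multiple testing: this is an exploratory ranking, not a
confirmatory screen, and the merge threshold is a mining knob, not an error
rate. Terms with `K = 0` are never tested or reported. A term untested in a
list (no annotated gene there) is `NA`, deliberately distinct from p = 1 in
every export.

## Semantic similarity

Information content is the negative natural log of the propagated annotation
frequency, `IC(t) = -ln(|genes(t)| / |genes(root)|)`, computed over the
analysis universe by default (configurable to the full annotation corpus —
the corpus choice is underdetermined in the field and the analysis universe
keeps IC aligned with the tests). IC(root) = 0; unannotated terms get no
entry and similarity lookups on them fail loudly with the term named.

Four IC-based pairwise measures go through the most informative common
ancestor `m` (ties broken lexicographically): Resnik `IC(m)/max_ic`
(normalised by the corpus maximum so all measures live on [0, 1] and
`d = 1 - s` is a usable clustering distance), Lin `2 IC(m)/(IC(a)+IC(b))`
(defined 0 when both terms are the root), Rel (Lin weighted by `1 - p(m)`),
and Jiang in the bounded form `1 - min(1, IC(a)+IC(b)-2 IC(m))`. Wang's
measure is purely topological: S-values propagate from the term through its
ancestor sub-DAG (`S = 1` at the term; at each ancestor, the maximum of
child S-values scaled by the relation weight, 0.8 for `is_a`, 0.6 for
`part_of`), and the similarity is the shared-ancestor S-mass over the two
total S-masses. Self-similarity is exactly 1; annotations play no role, and
a test recomputes Wang matrices under shuffled corpora to pin that down.

Between term sets, with `M` the pairwise similarity matrix: `max`, `avg`,
`rcmax` (larger of the two directional mean-of-maxima), and the default
`BMA = (sum_i max_j M_ij + sum_j max_i M_ij)/(m+n)` — each term's best match
in the other set, symmetrised. All four are tested against a direct
double-loop oracle on random matrices.

Matrices are clamped to [0, 1] after floating-point rounding and are exactly
symmetric by construction.

## Clustering, cutting, naming

The workflow default — Wang distance with `ward.D2` aggregation — applies
Ward's minimum-variance criterion to squared dissimilarities and reports
heights on the original scale; merge heights are pinned to a brute-force
Lance-Williams oracle in the tests. Static cuts (`k` or `h`) relabel
clusters by first appearance along the dendrogram leaf order, so cluster 1
is always the leftmost displayed.

The dynamic cut is an adaptive branch detector in the spirit of dynamic tree
cutting. The committed rule: clusters are the maximal branches lying entirely
below an adaptive height `h0 = frac * max(height)`, with `frac` stepping
0.95, 0.90, 0.85, 0.80, 0.75 for `deep_split` 0-4 — every merge above `h0`
only attaches such branches to their surroundings, which operationalises
"branches separated from their surroundings by their merge profile".
Branches smaller than `min_cluster_size` (default 2) are left unassigned
(label 0) rather than force-merged. An earlier draft split branches by the
relative height gap at each node; on Ward trees of realistic similarity
matrices those relative gaps are uniformly small and the rule degenerated to
a single cluster at every sensitivity, so the height-quantile formulation
was adopted instead. Defaults (`min_cluster_size = 2`, `deep_split = 2`) are
recorded in the run log of every run.

Clusters are renamed by their **most specific common ancestor**: among the
reflexive common ancestors of all members, the term of maximal level, ties
broken by maximal IC, then lexicographically. "First common ancestor" is
ambiguous between shallowest and deepest; the deepest is the informative one
(the shallowest is usually the root), and the naming is tested to be an
ancestor-or-self of every member. Cluster-vs-cluster similarity applies the
set combination (default BMA) to every cluster pair, excluding unassigned
leaves.

Classical (Torgerson) MDS double-centres the squared distance matrix and
eigendecomposes; negative eigenvalues — the non-Euclidean part of `1 - s` —
are truncated to zero and their share of the absolute eigenvalue mass is
reported as a distortion diagnostic on the returned coordinates. Embeddings
of genuinely Euclidean configurations are recovered to rigid motion
(Procrustes residual below 1e-6 in the tests).

## Reporting

Every figure (count barchart, upset summary, term heatmap of `-log10 p` with
IC sidebar in dendrogram leaf order, cluster heatmap of member counts, MDS
scatter with cluster-size dot areas) is written alongside a TSV/JSON twin
carrying exactly the plotted numbers; all assertions in the test suite read
the twins, never pixels. The run log captures input md5 digests, the
effective configuration and per-stage counts; it is the only output with a
timestamp, and reruns of identical inputs are byte-identical in every other
TSV/JSON artifact (a tested property).

## The synthetic-data generator

The generator emulates the *shape* of a multi-comparison expression study at
desk scale, with one RNG stream per component (ontology, annotations, study
lists) derived from a master seed, so regenerating one component never
perturbs another. Defaults, chosen once as a realistic miniature:

| knob | default | why |
|---|---|---|
| `n_terms`, `max_depth` | 300, 8 | a namespace large enough for non-trivial topology, small enough for seconds-scale runs |
| `part_of_fraction` | 0.15 | minority relation, as in real GO |
| `extra_parent_prob` | 0.3 | multiple inheritance without degenerate DAGs |
| `n_genes` | 2000 | a plausible expressed-gene background at 1/10 scale |
| `terms_per_gene_lambda` | 2 (1 + Poisson) | a few direct terms per gene |
| `depth_decay` | 0.65 | direct-annotation counts decay geometrically with depth, as in real corpora |
| `n_lists`, `list_size` | 3, 200 | a three-contrast design at 1/10 scale |
| `planted_odds` | 15 | strong but not deterministic over-representation |
| `planted_min_genes` | 25 | a stable annotation base for each planted term |

Parents are drawn only from strictly shallower depths, so the DAG is acyclic
by construction and each term's longest-path level equals its assigned
depth. Interest lists sample genes without replacement with weight
`planted_odds` on carriers of the list's planted term; `planted_odds = 1`
reduces to uniform sampling, and a ground-truth manifest is written next to
the lists.

What the generator does *not* emulate: real GO's scale (tens of thousands of
terms), its long-tailed branching and annotation distributions, evidence-code
structure, obsolete/alt-id churn, or correlated annotation between related
genes. Passing the planted-recovery tests therefore demonstrates that the
machinery detects a known signal under controlled conditions — not that any
particular biological dataset will yield stable clusters.

Planted-signal recovery is checked with the *classic* test: the planted term
must appear in the merged table (p < 0.01) and rank first in its list. That
is deliberate. Elim's purpose is to hand a parent's inheritance signal to
its significant children; since carriers of the planted term are boosted
uniformly, the planted term's own children are themselves enriched, elim
eliminates their genes from the planted term, and the top rank legitimately
moves within the planted branch. The recovery property belongs to the direct
test; the elim behaviour is pinned instead by hand-worked two-level and
sibling fixtures.

## Numerical conventions, in one place

* Hypergeometric tails in log space; `x = 0` returns exactly 1.
* Resnik normalised by corpus max IC; Lin/Rel 0 for root-root pairs; Jiang
  bounded into [0, 1]; all matrices clamped to [0, 1] and symmetric.
* Ties: elim processing order by ascending term id within a level; MICA by
  lexicographic id; cluster naming by level, then IC, then id; cluster labels
  by dendrogram leaf order.
* Degenerate inputs error early and specifically: empty interest lists,
  empty term sets, unannotated terms in similarity lookups, invalid
  contingency counts, malformed GAF/TSV rows (with line numbers).
* Problem sizes in the packaged checks — exhaustive hypergeometric grids to
  `N = 30`, 8-leaf Ward oracles over 50 seeds, 20-seed recovery runs, and the
  300-term/2000-gene pipeline — are the package's chosen balance between
  coverage and a seconds-scale default test run.

## Known limitations

* Only `is_a`/`part_of` are interpreted; `regulates`-style relations are
  dropped, which slightly flattens real BP neighbourhoods.
* Only classic and elim are implemented; weight/parent-child style algorithms
  are an extension point behind the algorithm argument.
* The dynamic cut is a contract-level reimplementation of adaptive branch
  detection, not a port of any specific reference implementation; cluster
  counts on real data will differ from tools using other variants.
* No multiple-testing correction, by design; treat merged tables as ranked
  exploration, not inference.
* Identifier spaces are taken verbatim; cross-database id mapping and live
  annotation retrieval are out of scope (inputs are files).
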