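---
title: "Comorbidity gene-set and network analysis: models, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comorbidity gene-set and network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorbidnet)
```

## The problem

Two clinically comorbid diseases — the motivating case is Alzheimer's
disease co-occurring with major depressive disorder — often share part of
their genetic architecture. Given a curated susceptibility gene list for
each disease, `comorbidnet` asks three questions at increasing levels of
biological organisation: which genes are shared; which biochemical pathways
are over-represented in each list and how do those pathways interlock
("cross-talk"); and which genes *outside* both lists are so densely
connected to the shared genes in the protein–protein interactome that they
are credible novel candidates for both diseases.

This vignette documents the models, the tunable parameters and their
defaults, the synthetic benchmark, and the numerical and design choices a
maintainer would want to know.

## Gene-set assembly

Gene sets are keyed by positive integer Entrez identifiers; symbols and
provenance tags are carried as metadata but never used for matching, since
symbol aliasing makes symbol joins ambiguity-prone. All outputs are sorted
by ascending gene ID so repeated runs produce byte-identical files.

Two inclusion routes are supported, reflecting how such lists are built in
practice:

* a curated-database route whose records carry a gene–disease association
  (GDA) confidence score in [0, 1] — records pass when their score exceeds
  the cutoff (`filter_by_gda()`, default 0.2, **strict** inequality: a score
  of exactly 0.2 is excluded, matching the "score above 0.2" convention; a
  flag switches to ≥);
* a literature-curation route whose records carry no score.

`apply_gda_policy()` implements the union of the routes: unscored records
pass untouched, scored records must clear the cutoff. This is the behaviour
`run_all()` uses, because a gene reported by the literature should not be
discarded merely because a database also lists it with a low score; the
plain filter remains available for the strict database-only reading.
Merging unions provenance tags and keeps the maximum score per gene;
`|A ∪ B| + |A ∩ B| = |A| + |B|` holds exactly and is property-tested.

## Over-representation analysis

For a query of $n$ genes (after restriction to the background universe of
$N$ genes — query genes outside the background are dropped, the standard
ORA convention) and a pathway with $K$ members of which $k$ are in the
query, the enrichment p-value is the one-sided upper tail

$$p = P(X \ge k), \qquad X \sim \mathrm{Hypergeometric}(N, K, n),$$

computed by `stats::phyper`. Only over-representation is tested. P-values
are adjusted across the whole collection with Benjamini–Hochberg
(`stats::p.adjust`), and a pathway is significant when FDR < `alpha`
(default 0.05). Adjustment is applied per disease per collection — two
diseases are two independent multiple-testing families, mirroring two
separate runs of an enrichment tool — never pooled across diseases.

The background defaults to the union of all pathway members, the only
universe derivable from a GMT file alone; an explicit larger universe can be
supplied (and the synthetic generator does supply its full gene universe).
The test suite pins these statistics to independent oracles: exhaustive
enumeration of every $n$-subset for $N \le 12$, log-binomial summation to
relative tolerance $10^{-10}$ for $N \le 200$, and a naive hand-rolled
step-up for BH.

`classify_pathways()` partitions significant pathways into shared
(significant in both diseases) and disease-specific (exactly one); the
partition identity $|\mathrm{sig}_A| = |\mathrm{shared}| +
|A\text{-specific}|$ is exact. Term *counts* against living annotation
databases (GO, KEGG) drift with snapshot versions; the package therefore
treats published counts of enriched terms as recorded context, not as
reproduction targets, and its tests only ever assert identities and
planted-truth recovery.

## Pathway cross-talk

Pathway pairs are scored on their **disease-gene-restricted** memberships:
$A$ = (pathway members) ∩ (disease-associated genes), because the cross-talk
network is built from the disease genes' perspective and published
per-pathway tables report disease-gene counts. A flag
(`restrict_memberships(collection, NULL)`) switches to full-membership mode,
since the restricted-vs-full choice is genuinely ambiguous in parts of the
cross-talk literature.

Two measurements are computed per pair:

$$JC = \frac{|A\cap B|}{|A\cup B|}, \qquad
  OC = \frac{|A\cap B|}{\min(|A|,|B|)},$$

with $JC \le OC$ always, $JC = 1$ iff the sets are equal, and $OC = 1$ iff
one contains the other (property-tested on random sets). An edge is kept
when both pathways have at least `min_genes` (default 3) restricted members
and share at least `min_shared` (default 2) genes — the common convention of
the cross-talk literature; both thresholds are configurable because
published analyses rarely state their exact pruning rule. The edge weight is
the arithmetic mean $(JC + OC)/2$: both coefficients are computed and
reported, and the mean is a symmetric, scale-preserving combination when no
combination rule is prescribed. Raising either threshold can only remove
edges (monotone filtering, tested), and the result is independent of
pathway input order because edges are canonicalised (`pathway_a <
pathway_b`) and sorted.

`build_tripartite()` attaches genes to the retained pathways: for the
shared-pathway network the attached set is the shared genes; for the
disease-specific variant it is all disease genes, with each gene's node
class (shared / disease A / disease B) recorded for downstream colouring.
Networks export to GraphML (full attributes), SIF (topology only) and TSV
(lossless pair of tables), and `read_network()` round-trips them.

## Interactome analysis and candidate prediction

Interactome cleaning enforces: no self-interactions, each unordered pair
stored once in `(min, max)` order, and an exclusion list removed entirely —
by default ubiquitin-C/B/D (Entrez 7316, 7314, 10537), whose non-specific
binding to degradation targets makes them artifactual hubs. Dropped
self-pairs and duplicates are counted on the object.

Disease subnetwork extraction uses the **edge-incident** rule by default:
keep every edge with at least one endpoint in the seed set, with the node
set being the endpoints of kept edges. This is the semantics under which a
few hundred seeds expand to thousands of nodes (their first neighbors); the
induced-subgraph rule (both endpoints seeds) is available behind
`extraction_rule = "induced"` for comparison. The overlap of two disease
networks is the **edge-set intersection**, and its node set is the endpoint
set of the common edges — deliberately not the intersection of the node
sets, which would retain nodes with no common interaction.

Under edge-incident extraction a small theorem drives the candidate score:
every overlap-network edge lies in both disease networks, so an edge
touching a node that is in neither seed set must have its *other* endpoint
in both seed sets — i.e. a shared gene. Hence every non-disease node of the
overlap network is adjacent only to shared genes there, and its
shared-gene-neighbor count equals its overlap-network degree. The test
suite asserts this on every synthetic instance.

`predict_candidates()` ranks all scored genes by descending shared-neighbor
count (ties broken by ascending gene ID, for determinism), flags genes
already in either disease list, and calls as novel candidates the unflagged
genes with count ≥ `min_count`. The default 6 encodes the
"degree greater than 5" convention for direct shared-gene interactions.
`extract_candidate_neighborhood()` then cuts out the candidate-incident
edges of the union disease network with node classes for visualisation;
edges among non-candidate neighbors are not included.

## The synthetic benchmark

The generator (`synthetic_config()` / `generate_synthetic()`) emulates the
statistical structure the pipeline assumes: an undirected simple background
interactome; two disease gene sets with a controlled overlap; candidate
nodes wired to a controlled number of shared genes; and pathway sets drawn
preferentially from the disease sets at a controlled enrichment fraction.
Defaults define the package's reference study conditions, chosen once as a
realistic desk-scale analogue of a genome-scale analysis:

| parameter | default | rationale |
|---|---|---|
| `n_genes` | 5,000 | universe large enough for hypergeometric tails to behave as at genome scale |
| `edge_model`, `edge_param` | Erdős–Rényi, 15,000 edges | mean degree 6, the order of sparse curated interactomes |
| `n_a`, `n_b`, `n_shared` | 100, 100, 30 | two moderate disease lists with a substantial but partial overlap |
| `n_candidates`, `candidate_wiring` | 20, 8 | planted candidates clear the default call threshold of 6 with margin |
| `n_pathways`, `pathway_size_range` | 50, 10–60 | typical curated-pathway sizes |
| `n_enriched_per_disease`, `enrichment_fraction` | 4, 0.8 | planted pathways draw 80% of members from their disease set |

Construction guarantees, in order: the shared subset is sampled first, so
$|A \cap B| = $ `n_shared` exactly; candidates are sampled outside both
disease sets; background edges between candidates and disease genes are
removed *before* wiring each candidate to exactly `candidate_wiring`
sampled shared genes, so the noise-free shared-neighbor count of each
planted candidate is exactly its wiring and recovery at any threshold up to
that wiring is guaranteed, with nothing else in the graph plausibly
reaching the threshold by chance (expected shared-neighbor count of a
background node ≈ 0.04). A planted pathway of size $s$ takes
$\lceil 0.8 s \rceil$ members from its disease set; at the default query
and universe sizes the hypergeometric tail of such a pathway is far below
any BH cutoff, so all planted pathways are significant by construction.
Because the 30 shared genes belong to both disease sets, pathways planted
for one disease are often significant for the other as well — the generator
models shared enrichment, which is the comorbidity setting of interest.

One integer seed drives a single RNG stream (the caller's RNG state is
saved and restored); writing the dataset and re-reading it round-trips all
truth labels, and two runs from the same seed are byte-identical.

`rewire_network()` is the noise model: a fraction `rate` of edges is
replaced by uniformly random non-self, non-duplicate pairs. The edge count
is conserved; the degree sequence is deliberately *not* (candidate wiring
should be destroyed by noise, not preserved by a degree-preserving swap).
With wiring 8 and call threshold 6, expected recall under rate $r$ is
approximately $P(\mathrm{Bin}(8, 1-r) \ge 6)$ — about 0.96, 0.55, 0.14 at
$r = 0.1, 0.3, 0.5$ — and measured recall tracks this closely, decreasing
monotonically in $r$.

What the generator does **not** emulate: the heavy-tailed degree
distribution of real interactomes (a preferential-attachment mode exists
but is not the default), correlated study-bias edges, gene-family pathway
overlap structure, and expression data (cell-type-specific expression
analysis is out of the package's scope). Passing tests therefore
demonstrate correctness of the algorithms under controlled conditions, not
biological validity of any particular real-data finding.

## Numerical and degenerate-case choices

* `hypergeom_pvalue(k = 0)` returns exactly 1; bounds violations raise a
  classed error rather than returning `NaN`.
* Raw p-values of exactly 0 are rejected by `bh_adjust()` — a true zero
  indicates an upstream error in this pipeline.
* `jaccard()` on two empty sets and `overlap_coefficient()` on any empty
  set raise classed errors (0/0); restricted memberships may legitimately
  be empty and such pathways simply cannot form edges.
* An enrichment query that is empty after background restriction raises
  `comorbidnet_empty_query` instead of silently returning all-1 p-values.
* Edge-list headers are auto-detected as a non-integer first line; a
  single-line file that does not parse as IDs is therefore read as an
  empty interactome, while unparsable IDs on later lines are an error.
* All ranking and file outputs are deterministically ordered; no timestamps
  are written into data files.

## Problem sizes used in validation

The shipped test-and-acceptance workloads run at the reference conditions
above (5,000-gene universe) for pipeline-level checks, with 100 generator
seeds per rewiring rate for recovery curves, 500 replicate null queries for
false-positive control, and a 300-gene miniature configuration for
per-module unit tests. The whole suite completes in a few minutes on one
CPU.

## Known limitations

* Entrez integer IDs are the only namespace; no identifier mapping is
  provided or attempted.
* ORA only: no ranked (GSEA-style) testing, no ontology-graph redundancy
  reduction.
* The cross-talk pruning thresholds and the JC/OC combination rule are
  conventions, exposed as parameters, not inferences from data.
* Candidate prioritisation uses direct neighbors only — no diffusion,
  random-walk or shortest-path scoring.
* Published enriched-term counts and network figures built on specific
  annotation-database snapshots are context, not targets; they cannot be
  regenerated from a GMT-agnostic implementation and are excluded from the
  package's claims.
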