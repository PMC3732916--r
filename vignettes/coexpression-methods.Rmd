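---
title: "Methods: co-expression networks, their topology, and the synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression networks, their topology, and the synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

coexflow implements a complete hard-threshold gene co-expression analysis
for multi-condition transcriptome compendia, of the kind assembled for
comparative studies across distant photosynthetic species (an alga, a moss,
an angiosperm). This vignette is the package's own account of the methods:
the statistical model behind each stage, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the numerical decisions taken where the procedure leaves freedom.

## 1. Differential-gene selection

Expression is taken as a non-negative gene-by-sample matrix (FPKM for
RNA-seq-like samples, normalized intensities for arrays; upstream
quantification and normalization are out of scope). For a contrast between
a condition and its control, each side is summarized by the log expression
`ln(mean + pseudocount)` and the delta-method variance of the log,

```
Var(ln X) ≈ Var(X) / (mean + pseudocount)^2 ,
```

with `Var(X)` the sample variance across replicates. A gene is selected
when at least one contrast satisfies both

* `|log ratio| >= ln(fold_threshold)` with `fold_threshold = 2`, and
* `|z| >= z_threshold` with `z = log_ratio / sqrt(var_cond + var_ctrl)`
  and `z_threshold = 2` (roughly a two-sided 95% criterion).

Choices worth recording:

* Both boundaries are **inclusive**: a gene at exactly 2-fold is selected.
  The conventional reading of "a fold-change criterion of two".
* `pseudocount = 1` expression unit by default, guarding `log(0)`;
  configurable, and set to 0 in tests that exercise exact ratios.
* Unreplicated samples use a Poisson-like fallback `Var(X) = mean(X)`,
  since public compendia often include unreplicated conditions; it can be
  disabled, in which case the z criterion reduces to the fold criterion.
* When both variances are zero (noise-free synthetic data), the z test is
  treated as passed provided the fold criterion holds; otherwise noise-free
  data could never select anything.
* No multiple-testing correction is applied at this stage; the selection is
  a noise filter ahead of network construction, not an inference.

## 2. Network construction and threshold selection

Co-expression is the absolute Pearson correlation `|r|` between expression
profiles across **all** samples jointly (not per-experiment averaging).
An edge links two selected genes when `|r| >= tau`. Genes with no
surviving edge are dropped; all node counts refer to connected genes.

The threshold is not fixed a priori. Following the scale-free criterion, a
grid of candidate thresholds (default 0.50-0.99, step 0.01) is scanned; at
each, the degree distribution `P(k)` over distinct observed degrees
(`k >= 1`, isolated nodes excluded, no log-binning) is regressed as
`log10 P(k) ~ log10 k`. A power-law (scale-free) network is linear on
these axes, and the fit's R² measures how scale-free the thresholded
network is. Among thresholds whose mean degree `2E/N` lies in a band
around the target density of ~20 neighbors per gene (default band
`[15, 25]`), the threshold maximizing R² is selected.

Decisions:

* Ties in R² break toward the **higher** threshold (the sparser, more
  stringent network).
* If no grid threshold reaches the band — e.g. a degenerate matrix where
  all correlations are equal — the threshold minimizing
  `|mean degree − target|` is returned and a warning is emitted; the full
  scan is always returned as an audit trail.
* Fits on fewer than 3 distinct degrees are flagged `low_support` (two
  points fit any line); a single degree reports R² = 0 rather than NA so
  the scan remains comparable.
* The slope p-value is the two-sided t-test on the regression slope.

Networks export as TSV edge lists (round-trippable), Cytoscape SIF, and
GraphML with a `weight` attribute.

## 3. Hubs and neighborhoods

Hub scores are Kleinberg (HITS) hub scores. On an undirected graph the
hub and authority vectors coincide with the principal eigenvector of the
adjacency matrix; the package computes it by power iteration (tolerance
1e-10, max 1000 iterations) per connected component, scaling each
component's unit eigenvector by its leading eigenvalue before
max-normalizing globally to 1. A positive diagonal shift is applied during
iteration because bipartite components (stars, trees) otherwise oscillate
between the two eigenvectors of ±λ. The binary adjacency is the default
(weights behind a flag), matching common tool behaviour. A degree-based
score is also provided, since "hub score" is sometimes read as degree; the
eigenvector score is the default.

Hubs are the top 5% of scores: `ceiling(0.05 n)` genes, with all genes
tied at the cutoff included (so ties can enlarge the set).

Neighborhoods are breadth-first balls: all genes within shortest-path
distance `k` (default 3 edges) of any focal gene, the focal genes included
at distance 0. For neighborhoods of hundreds of genes, including or
excluding the seeds does not move enrichment results appreciably, but the
inclusion is recorded.

## 4. Enrichment and cross-species comparison

Neighborhood function is read out by one-sided hypergeometric
over-representation tests of each annotation term against the full
annotated genome as background: `p = P(X >= x)` with
`X ~ Hypergeometric(N, K, n)`. Terms absent from the target are omitted;
Benjamini-Hochberg q-values are computed across the tested terms
(`q <= 0.05` calls a term enriched; the cutoff is a package default, not a
value inherited from any particular study). Annotations are treated as
flat gene-to-term tables, as appropriate for Pfam-derived annotation of
less-studied genomes; DAG-aware propagation is out of scope.

Across species ordered by evolutionary position (e.g. alga, moss,
angiosperm), a term is classified as:

* `conserved_all` — enriched in every species;
* `shared_derived` — enriched in a contiguous suffix of **at least two**
  later species (a process gained once and retained); a term enriched only
  in the final species is *not* shared by anything and falls to
  `species_specific`;
* `species_specific` — any other pattern with at least one enrichment;
* `not_enriched` — retained for completeness.

Non-contiguous patterns (first and third species but not the second) are
deliberately `species_specific`: without a parsimony model, a
gain-loss-regain narrative is not distinguishable from noise.

Functional specialization of a gene family is summarized by the
marker-correlation matrix: `|r|` of each focal (family) gene against a
panel of process-marker genes, grouped by average-linkage hierarchical
clustering of the rows (Euclidean distance), cut at 2 groups by default.
Rows are processed in lexicographic gene order so the grouping is
deterministic.

## 5. Promoter motif enrichment

Motifs are IUPAC strings scanned over both strands with overlapping
matches counted. Two wildcard rules are fixed for determinism: a pattern
`N` matches any base including `N`; an `N` in the subject sequence is
matched by nothing else. Enrichment compares motif **presence** (at least
one site per promoter, not site counts) in target vs background gene
groups with a one-sided Fisher's exact test. Default promoter length in
the generator is 1000 bp. The binding-site consensus strings themselves
are user configuration: the package hard-codes no motif.

## 6. Distance phylogenetics

Protein alignments (supplied aligned; alignment computation is out of
scope) yield p-distances — mismatches over pairwise-comparable,
gap-free-in-both columns — or Poisson-corrected distances
`−ln(1 − p)`, capped at 5.0 at saturation with a warning. Trees are built
by classic neighbor joining; negative branch lengths are clamped to zero
with the deficit moved to the adjacent branch, preserving path lengths.
Bootstrap support resamples alignment columns with replacement (1000
replicates by convention; tests and examples use fewer), rebuilds the NJ
tree per replicate, and reports the majority-rule consensus with supports
as percentages of replicates containing each internal bipartition.
Rate-heterogeneous empirical substitution models (JTT + gamma) are
deliberately not implemented: the agglomeration, bootstrap and consensus
machinery is model-agnostic, and the simple distances keep the module
self-contained and testable.

## 7. The synthetic benchmark

Every stage is exercised end-to-end on generated data with planted
structure, since the compendia this methodology targets are terabyte-scale
external archives. The generator emulates:

* **Modules** — gene sets sharing a condition-response signal. Each module
  is assigned a disjoint (round-robin) subset of conditions; responsive
  conditions change the condition mean by a fold change drawn uniformly
  from `fold_change_range` (default `[2, 6]`), up- or down-regulated with
  equal probability. Within-module correlation is induced by adding
  gene-specific Gaussian noise to the shared signal, with the noise
  variance solved from the target correlation via
  `rho = var(signal) / (var(signal) + var(noise))` — a closed-form knob
  verifiable by Monte Carlo. Genes get individual positive scale factors,
  so zero-noise modules are identical up to scale.
* **Hubs** — genes whose profile is the average of several modules'
  signals, i.e. members bridging modules.
* **Background** — genes fluctuating around baseline with a configurable
  common correlation.
* **Annotations** — module genes carry their module's terms exactly;
  background genes pick terms from a pool independently at a noise rate.
* **Promoters** — i.i.d. uniform A/C/G/T with one motif instance planted
  at a random position and strand at given target/background rates; chance
  matches are left in, so scanners face a realistic false-positive floor.
* **Alignments** — sequences evolved along a given tree under a 20-state
  symmetric substitution process, so short-branch p-distances approach
  path lengths.

Defaults chosen once as realistic study conditions: baseline expression 10
(FPKM-like), `fold_change_range = [2, 6]`, balanced up/down responses,
background noise SD 1, 3 replicates per condition in examples. The
balanced up/down default matters: with up-only responses, two modules
responding to disjoint condition sets become strongly *anti*-correlated
through their shared baseline samples,
which no real compendium of independent processes shows; balanced
responses center profiles near baseline and push between-module
correlation toward zero. Values are floored at zero after noise, as
expression units are non-negative; with balanced responses the flooring
touches only a few percent of entries and does not measurably bias planted
correlations.

What the generator does **not** emulate — and therefore what passing tests
do not certify about real data: count-based sampling noise (no read-level
simulation), platform batch effects across the mixed RNA-seq/array
compendium, correlated non-module structure (housekeeping programs),
annotation incompleteness or bias, and the evolutionary dynamics of gene
family expansion (orthology is declared, not evolved).

## 8. Problem sizes and determinism

The test suite and the acceptance script run the full chain on a
2000-gene compendium (5 modules of 50 genes, 20 conditions × 3
replicates), with smaller instances for oracle-equivalence checks
(exhaustive enumeration up to universe size 12-15, dense
eigen-decomposition up to 50 nodes, Floyd-Warshall up to 200 nodes) and
Monte-Carlo recovery checks over 10-20 seeds — sizes at which every oracle
is exact and the whole suite runs in well under a minute. All generators
take explicit seeds and restore the caller's RNG state; identical
configuration and seed reproduce byte-identical outputs, which the
pipeline manifest records as per-file checksums.

## 9. Known limitations

* Hard thresholding discards the weight continuum; soft-threshold
  (WGCNA-style) networks are out of scope by design.
* The scale-free R² on raw (unbinned) degree frequencies is noisy for
  small networks; the `low_support` flag marks fits that should not be
  trusted, but the scan still reports them.
* HITS scores concentrate on the dominant component; in highly fragmented
  networks, per-component scaling by the leading eigenvalue is a
  convention, not a theorem.
* The conservation classifier is a pattern rule over enrichment flags,
  not an ancestral-state reconstruction.
* p/Poisson distances ignore among-site rate variation; deep divergences
  will be compressed relative to model-based distances.
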