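---
title: "Methods: from assembled transcripts to an inferred interactome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from assembled transcripts to an inferred interactome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unitome)
```

unitome is a post-assembly toolkit for de novo transcriptome projects in
non-model organisms — the setting where a researcher has a few tissue
libraries, a de novo assembly clustered into unigenes, tabular outputs from
BLAST and HMMER, and no genome, no replicates, and no curated interactome.
This vignette explains each method the package implements, the assumptions
behind it, the tunable parameters and their defaults, and what the
synthetic-data generator does and does not emulate.

## Assembly statistics

`assembly_stats()` reports the sequence count, total length, mean length
and N50. N50 is defined inclusively: sort lengths in decreasing order and
take the first length at which the cumulative sum reaches *at least* half
the total. The inclusive convention matters only at exact-half ties, but it
is the convention under which published assembly tables are reproducible.
Mean lengths are rounded to the nearest integer with ties away from zero
(banker's rounding would shift half-integer means down half the time).

## Protein prediction: six-frame longest ORF

`six_frame_orfs()` enumerates every maximal stop-free codon run in the six
reading frames; `select_protein()` keeps the single longest and discards it
if shorter than `min_aa` (default 30 aa). Design choices:

* **No start-codon requirement.** Assembled unigenes are frequently
  5'-truncated, so requiring ATG would systematically discard genuine
  coding fragments. ORFs are stop-to-stop, with open 5' and 3' ends at the
  sequence boundaries.
* **Ambiguity.** Any codon containing `N` translates to `X`, and `X` never
  terminates a run. This slightly favors runs through ambiguous regions
  over splitting them, which matches the intent of "longest ORF".
* **Determinism.** Equal-length candidates are resolved by frame order
  `+1, +2, +3, -1, -2, -3`, then smallest forward-strand start. All
  coordinates are reported 0-based half-open on the forward strand, so the
  reported interval always re-translates to the reported protein.
* Trailing partial codons are ignored.

A consequence worth knowing: under the stop-to-stop rule, essentially every
random sequence longer than ~400 nt contains some ≥30-aa run (stop codons
occur at ~3/64 per codon), so the 30-aa filter is a guard against spurious
micro-ORFs on short unigenes, not a strong coding classifier.

## Expression: FPKM and no-replicate differential expression

`compute_fpkm()` implements FPKM = C·10⁹/(N·L) — fragments scaled per
kilobase of transcript (10³) and per million mapped fragments (10⁶).

`call_de()` compares two *single* libraries. With no replication, the
variance cannot be estimated within condition; the package adopts the
classic blind strategy: treat the two conditions as if they were
replicates, estimate a per-gene method-of-moments dispersion from that
pair, and fit the mean–dispersion relation α(μ) = a₀/μ + a₁ by least
squares of the raw dispersion against 1/μ (`fit_dispersion()`, using genes
with normalized mean ≥ 1, floored at α_min = 10⁻⁸). Genes that are truly
differential inflate this pooled dispersion, so the resulting test is
deliberately conservative — the standard and defensible failure mode for
no-replicate designs.

The test itself (`nb_exact_test()`) conditions on the total count
kA + kB: both conditions share the dispersion evaluated at the pooled
normalized mean, the joint NB probability of every split of the total is
computed in log space, and the two-sided p-value is the probability mass of
all splits no more likely than the observed one. For very large totals the
support is truncated where the neglected tails hold < 10⁻¹² of the mass.
Counts are normalized by median-of-ratios size factors
(`size_factors()`); raw counts, not FPKM, feed the NB machinery, because
the NB model is a model of counts.

Calls use FDR q < 0.05 (Benjamini–Hochberg) and |log2 fold change| > 1
(strict), the conventional thresholds for this design; both are arguments.
The fold change is computed on normalized counts with a pseudo-count of
0.5 per condition, which keeps one-sided zeros finite while preserving
direction.

Calibration, measured by the package's own tests on seeded simulations: on
a 2,000-gene null the pipeline flags ≤ 1% of genes; with 50 genes planted
at |log2fc| = 3, dispersion 0.05 and means ≥ 200 it achieves precision and
recall ≥ 0.8. At smaller planted effects (|log2fc| = 2, the bundle
default) recall is substantially lower — conservatism is the price of no
replication.

## Annotation transfer

`transfer_best_hit()` implements "annotate from the most similar protein":
per query, smallest E-value wins, ties broken by larger bit score, then
lexicographically smallest subject id. E-value (not percent identity) is
the similarity currency because it is also the filtering currency — both
homology and domain hits are pre-filtered at E < 10⁻⁵, the conventional
reliable-hit threshold. `assign_domains()` collapses surviving domain hits
into per-protein sets of unversioned Pfam accessions; version suffixes are
stripped (`PF13465.1` → `PF13465`) because domain-interaction compendia key
on unversioned accessions. GO/KEGG/COG attachment is a join of best-hit
subjects against a user-supplied subject→term map; the upstream annotation
pipelines themselves are out of scope.

## Interactome inference from domain–domain interactions

`build_network()` connects proteins p ≠ q whenever some domain of p is
known to interact with some domain of q (unordered pairs; a
self-interacting domain connects two different proteins that both carry
it). The graph is simple: no self-loops — protein "interactions" here mean
pairs of distinct gene products, and the topology statistics below assume
a simple graph. Every edge records its supporting domain pairs as
evidence. Which interaction confidence classes to accept is exposed in
`read_ddi_table()` and defaults to all classes, since inference projects
of this kind rarely state a restriction.

`topology_report()` computes:

* the degree histogram and mean degree;
* a power-law exponent b for P(k) ~ k⁻ᵇ, fitted by least squares of
  log₁₀P(k) on log₁₀k over degrees with nonzero count — the estimator used
  by the common network-analysis GUI plugins, chosen for comparability
  with published interactome exponents; a discrete maximum-likelihood
  variant is available via `fit_power_law(method = "mle")` for users who
  want the statistically preferable estimator;
* the unordered shortest-path length histogram (unweighted BFS);
* per-node topological coefficients: for node n of degree k_n, the mean
  over all nodes m sharing ≥ 1 neighbor with n of J(n,m)/k_n, where
  J(n,m) is the number of shared neighbors plus 1 if n and m are
  adjacent; nodes with no co-neighbored partner get 0;
* shortest-path betweenness, unnormalized by default (raw dependency
  counts), with a flag for (n−1)(n−2)/2 normalization.

`find_hubs()` ranks nodes by degree with deterministic id tie-breaks.

## Steiner subnetwork extraction

Given seed genes (e.g. all genes annotated to a structure of interest),
`steiner_subnetwork()` extracts a minimal subnetwork connecting them
through their shortest paths. The Steiner minimal tree is NP-hard; the
package uses the shortest-path heuristic (Takahashi–Matsuyama): seed the
tree with the smallest-id terminal, then repeatedly attach the terminal
closest (unit edge weights, BFS distance) to the current tree via one
shortest path, breaking all ties by node id. The heuristic is a
2(1−1/|T|)-approximation; the test suite verifies the ≤ 2× bound against
an exhaustive oracle on small graphs. Terminals absent from the network
are dropped with a warning; terminals spanning several components yield a
forest, one tree per component, with a warning — silent failure would be
worse than either convention.

## Enrichment

`fisher_exact_2x2()` evaluates the hypergeometric distribution in log
space (via the log-gamma machinery underlying `dhyper`), so genome-scale
tables produce correct p-values in the 10⁻²⁰⁰ range rather than
underflowing to 0. The two-sided p-value sums all tables no more probable
than the observed one, with a 1+10⁻⁷ relative tolerance when comparing
probabilities to guard against ties broken by floating-point rounding.
`term_enrichment()` is one-sided (over-representation): enrichment asks
whether a term is over-represented, and the 2×2 cell construction
(k, n−k; K−k, N−n−K+k) makes the upper tail the only relevant one.
`compare_two_sets()` — contrasting a term's frequency between two gene
sets — is two-sided, because either set may be the richer one.
"Corrected p-value" is Benjamini–Hochberg throughout: it is the field
default for pathway enrichment, and matches the FDR vocabulary used for
the expression analysis.

## The synthetic-data generator

`simulate_bundle()` writes every input the pipeline consumes, with a truth
record sufficient to score every stage, so the whole toolkit is testable
without downloads. What it emulates, and how the defaults were chosen:

* **Unigenes** carry planted stop-to-stop ORFs of 30–80 aa (70%) or 4–24
  aa (30%, below the retention threshold, exercising the filter). Each
  ORF sits between explicit stop codons inside stop-dense `TTAA`-repeat
  padding (that 4-mer contains a stop within four codons in every frame
  on both strands), and ORF codons are rejection-sampled until the
  planted run is the strict six-frame maximum — so the recorded truth is
  unambiguous by construction, verified by a generator-internal scanner
  that shares no code with the ORF module.
* **Domain hits** draw 1–3 domains per protein from a 12-domain pool of
  common Pfam families, written in domtblout column positions with
  versioned accessions and decoy rows above the E-value cutoff.
* **The DDI table** is a random selection of domain pairs (plus one
  self-interacting domain); the true network is derived by an explicit
  all-pairs scan, independent of `build_network()`.
* **Counts** are NB with dispersion 0.05 (a typical well-measured
  library), log-uniform means in 50–1000, and 10% of genes planted
  differential at |log2fc| = 2.
* Each section draws from its own sub-stream (fixed offsets on the bundle
  seed), so adding a generator never perturbs existing outputs, and
  regeneration under the same seed is byte-identical.

What it does **not** emulate: read-level sequencing error, coverage-driven
assembly artifacts (chimeras, fragmentation, isoform collapse),
phylogenetic structure in homology hits, correlated domain co-occurrence,
or the heavy-tailed degree distributions of real interactomes. Passing
tests on bundles therefore demonstrate algorithmic correctness on clean
inputs, not robustness to assembly noise.

## Numerical and scale choices

Problem sizes in the shipped tests and acceptance script — 2,000-gene DE
simulations, 100-gene bundles, exhaustive small-graph enumeration to 5
nodes with sampling at 6–7 — were chosen as the smallest scales at which
each statistical property is cleanly measurable; all of them run on a
laptop core in minutes. Exponent-recovery checks use exact histograms
(counts proportional to k⁻ᵇ at 10¹² scale) so the fit is tested free of
sampling noise. The NB exact test truncates its support sum only beyond
totals of 50,000, where the neglected mass is below 10⁻¹².

## Known limitations

* The no-replicate test cannot distinguish biological variability from
  condition effects; its calls are best read as "large, consistent
  differences", and small fold changes are undetectable by design.
* Domain-interaction networks over-connect promiscuous domains (kinases,
  zinc fingers): two proteins sharing a common interacting domain pair are
  linked regardless of context, so hub degrees are upper bounds.
* The log–log least-squares power-law fit is biased for noisy sampled
  histograms; it is exact on exact histograms (which the tests verify) and
  is retained as the default for comparability, with MLE as the
  alternative.
* FPKM is reported for continuity with the transcriptomics literature;
  cross-sample comparisons inside the DE machinery use size-factor
  normalized counts, not FPKM.
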