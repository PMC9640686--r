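---
title: "Methods: pangenome construction and conservation profiling with streptopan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pangenome construction and conservation profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streptopan)
```

## Scope and model

`streptopan` implements a desk-scale bacterial pangenomics workflow of the
kind used for comparative analyses of *Streptomyces*: per-genome protein sets
are clustered into orthologous groups from pairwise sequence similarity, the
groups are profiled by conservation, and downstream modules interpret the
groups functionally (COG/KEGG/CAZyme/BGC conservation profiles,
domain-architecture classifiers, pathway completeness, strain clustering
from CAZyme presence–absence patterns).

The central definition is the orthologous group. Two proteins are orthologue
candidates when a local alignment between them reaches

* percent identity ≥ 80 (identical aligned columns / alignment length,
  gap columns included in the denominator — the BLAST `pident` convention),
* coverage ≥ 0.70 **on both sequences** (aligned span / sequence length),
* E-value < 1e-5.

Identity and coverage thresholds are inclusive, the E-value bound strict,
matching the inequality directions as usually printed. An undirected edge
joins a pair if *either* direction of their hit passes (no
reciprocal-best-hit requirement), and orthologous groups are the connected
components of that graph, singletons included. This is deliberately
single-linkage: components can in principle chain through intermediate
sequences, and no community detection is applied — the method's fidelity to
the connected-components definition is part of its contract. The stringent
80%/70% thresholds exist precisely to keep functionally distinct paralogues
(e.g. the many *Streptomyces* sigma factors) out of the same component;
their known cost is that orthologues conserved only around active-site
residues can be missed.

## Alignment

`local_align()` is Smith–Waterman over BLOSUM62 with affine gaps costing
`11 + g` for a gap of length `g` (the BLASTP 11/1 convention), computed by
Biostrings' C implementation. E-values for the built-in aligner use a
Karlin–Altschul approximation `E = K·m·n·exp(−λS)` with the standard gapped
BLOSUM62 parameters K = 0.041, λ = 0.267 and no edge-effect correction; this
is adequate because the E-value acts only as a filter and the
identity/coverage criteria dominate at desk scale. When hits are ingested
from a BLAST tabular file the file's E-values are authoritative, and the
14-column dialect (with `qlen`/`slen`) is required because dual coverage
cannot be computed without sequence lengths.

The all-vs-all stage prefilters candidate pairs to those sharing at least 2
exact 5-mers (computed by a sparse sequence-by-k-mer incidence matrix
product). The prefilter is a pure optimisation: the test suite compares the
prefiltered qualifying-pair set against an exhaustive, independently written
O(nm) dynamic-programming oracle and requires equality. Co-optimal
alignments are a real ambiguity — two tracebacks with equal score can differ
in identity and coverage — so exact-statistic comparisons are made on pairs
whose optimum is unique, and pair qualification is kept far from the
thresholds in the planted designs.

## Synthetic pangenomes

`generate_pangenome()` plants orthologous groups with known prevalence: each
group is one random ancestor sequence (i.i.d. uniform over the 20 standard
residues) plus per-genome copies mutated by substitution only. The spec's
`within_group_identity` is the target *pairwise* identity between members;
each copy therefore substitutes `(1 − identity)/2` of its positions so that
two siblings differ at about `1 − identity` of positions. Substitution-only
mutation keeps the planted identity exact by construction and makes the
80%-identity boundary testable deterministically; an indel model is
deliberately out of scope. Unrelated (strain-specific) proteins are drawn
independently: at length ≥ 100 the probability that two uniform random
sequences reach 80% identity over 70% mutual coverage is negligible, so
planted partitions are separable at the default thresholds.

Default study conditions are 20 genomes of roughly 200 proteins each
(150 core groups, accessory groups at 50% and 25% prevalence, 20 unique
proteins per genome) at within-group identity 0.9 and lengths 100–300
residues — a deliberately compressed but structurally faithful miniature of
a multi-hundred-genome pangenome: lengths sit at the low end of typical
bacterial proteins and proteome sizes are ~2.5% of a real *Streptomyces*
proteome. The generator does **not** emulate phylogenetic
correlation between genomes, gain/loss along a tree, indels, domain
shuffling, or sub-telomeric placement of accessory genes; recovery of
planted partitions with adjusted Rand index 1.0 therefore demonstrates the
correctness of the clustering machinery under controlled divergence, not
robustness to every feature of real data.

What the synthetic-data seed controls is everything: with `seed` fixed, the
FASTA output is byte-identical between runs.

## Conservation statistics

Prevalence is the number of distinct genomes holding at least one member of
a group. Labels are computed on the real-valued prevalence fraction with no
rounding: `core` is fraction ≥ 0.95 (so at 205 genomes, 195 genomes qualify
and 194 do not), `rare` is fraction < 0.05 (at 205 genomes, 10 or fewer),
`strict_core` is presence in every genome, and `single_copy_core`
additionally requires exactly one copy per genome. Conservation histograms
use twenty 5%-wide bins, left-open and right-closed — `(0, 0.05], …,
(0.95, 1]` — which is the binning that places "10 of 205" in the lowest bin
and strict-core groups in the top bin.

Accumulation curves resample genome orderings (default 100 permutations —
the number of orderings behind such curves is rarely stated in publications,
so it is an explicit, configurable parameter here) and count, after each
added genome, the groups seen so far (pangenome), the groups in all genomes
so far (strict core) and the groups in ≥ 95% of genomes so far (soft core).
Within one ordering the pangenome count is non-decreasing and the strict
core non-increasing; both are asserted for every sampled permutation in the
tests, and the exhaustive 3-genome enumeration is the oracle for the
sampled implementation.

The rare-count-vs-proteome-size correlation uses Spearman rank correlation:
the relationship is expected to be monotone, not linear, and rank
correlation is insensitive to the heavy right tail of proteome sizes. The
method is switchable. Percentages everywhere are rounded half-up (4.25 →
4.3), matching how such fractions are conventionally printed; base R's
banker's rounding would disagree on exact halves.

## Annotation profiles

Annotation tables are filtered at load time with independent E-value
thresholds of 1e-1 (Pfam/SMART domains) and 1e-10 (COG); rows are
deduplicated and every drop is accounted (`kept + dropped = input` is a
tested invariant). Multi-letter COG strings ("KT") contribute once per
letter by default, with a single-category mode (first letter) available;
KO-to-category rollup requires a user-supplied mapping because the KEGG
hierarchy is not bundled, and an exclusion list drops eukaryote-only or
secondary-metabolite categories from the rollup. CAZyme class statistics
use the population standard deviation for the coefficient of variation
(CV = SD/mean over the fixed, fully enumerated set of genomes); classes
absent from every genome have undefined CV and are reported as missing.

## Domain-architecture classifiers

Sigma factors: a protein is a σ70-family factor iff it has Sigma70_r2
(PF04542) and either Sigma70_r4 (PF04545) or Sigma70_r4_2 (PF08281);
carrying both Sigma70_r1_2 (PF00140) and Sigma70_r3 (PF04539) places it in
"group 1 or 2" (the two groups share the same minimal domain set and are not
distinguishable from architecture alone), Sigma70_r3 without Sigma70_r1_2 is
group 3, everything else group 4. PF00309/PF04963/PF04552 identify
σ54-family factors; σ70/σ54 double matches are reported for both families
with a warning since none are expected in streptomycetes. The whole rule is
tested over all 32 presence combinations against a hand-written table.

Transcription factors are classified by a priority-ordered architecture rule
table (required domains present, forbidden absent); proteins already called
sigma factors are excluded. The shipped `tf_rules.tsv` is a five-family
example catalogue for tests and demonstrations — a real analysis should
supply a full P2TF-style catalogue, whose schema is the same three-column
rule format.

Chaplins are proteins with a PF03777 hit surviving the Pfam threshold.
PPTases apply their own stricter threshold (PF01648 at E < 1e-3, strict) to
*raw* domain hits; Sfp-type calls require a second transferase domain,
operationalised as ≥ 2 envelope-non-overlapping qualifying hits where
overlap means any shared residue — a maximum-disjoint-interval count, since
no overlap tolerance is part of the published rule.

## KO assignment and pathway completeness

Standard KO assignment keeps rows with independent E-value < 1e-10 **and**
score at or above the KO-specific adaptive threshold, then retains the best
KO per protein (highest score; ties by smaller E-value, then lexicographic
KO — a deterministic, documented tie-break). The relaxed rule additionally
assigns, to proteins left unannotated by the standard rule, their
highest-score KO when its E-value is < 1e-80 (strict); relaxed mode is a
tested superset of standard mode.

Pathways are ordered steps with OR semantics over acceptable KO terms
(isoenzymes and subunits), and completeness is genome-level presence of
every step — copy number and synteny are deliberately ignored. The shipped
β-ketoadipate definitions encode the six-reaction protocatechuate and
catechol branches with their three shared terminal steps
(enol-lactone hydrolase, β-ketoadipate CoA-transferase, thiolase) using
conventional KEGG KO identifiers as editable defaults; they should be
verified against the current KEGG release before biological use, and all
tests run on synthetic definitions. The 2^6 enumeration (complete iff all
six steps present) and shared-step consistency between the branches are
both asserted exhaustively.

## CAZyme landscape

Families are selected when at least 70% of their member proteins belong to
groups at prevalence within [0.05, 0.55] — both boundaries inclusive, since
the selection is described as "between 5 and 55%" with an "at least" floor.
The presence–absence matrix keeps groups from selected families at
prevalence ≥ 0.05 and marks a strain 1 when it holds any member.

Strains are embedded in 2D from Jaccard distances between binary rows
(`dist(method = "binary")`; the metric is configurable). Two embedders are
provided: classical metric MDS (`cmdscale`, fully deterministic) as the
default, and a seeded force-directed layout of the k-nearest-neighbour
graph, which is the neighbourhood-graph family of embeddings that UMAP
belongs to. Clusters come from a classic DBSCAN over the embedding (noise
label −1, `minPts` = 5 by default). When no radius is given, `eps` is set
by a largest-gap heuristic: if the sorted pairwise embedding distances show
a single dominant gap (> 25% of the largest distance), `eps` is the gap
midpoint — the regime of well-separated blocks this analysis targets;
otherwise it falls back to 3× the median `minPts`-NN distance. Coincident
points are always connectable (`eps` floored at 1e-8), so a matrix of
identical rows forms one cluster. Planted two-block designs (40 strains,
5% bit-flip noise) are required to be recovered with zero misassigned
strains by both embedders.

## Pipeline and determinism

`run_pipeline()` chains the stages (proteomes → hits → graph → groups →
statistics → profiles → classifiers → pathways → landscape), writes one TSV
artefact and a row-count log entry per stage, skips annotation-dependent
stages with a notice when their inputs are absent, and freezes the resolved
configuration as JSON in the output directory. Given the same configuration
and seed, every artefact is byte-identical between runs; this is asserted in
the tests.

## Problem sizes used by the test suite

The suite validates at the scales the design targets: planted-group
recovery on 20 genomes × ~200 proteins; oracle equivalence on ≤ 50-protein
sets (the pure-R DP oracle is quadratic per pair) with 100 random graphs for
the component oracle; 100 sampled orderings for curve properties; exhaustive
enumerations (32 sigma architectures, 64 pathway-step combinations) wherever
the space is small enough to enumerate.

## Known limitations

* Single-linkage components chain by design; no community detection.
* The Karlin–Altschul E-value is an approximation without edge-effect or
  composition corrections; for publication-grade E-values ingest BLAST
  tables.
* The synthetic generator omits phylogenetic structure, indels and domain
  architecture, so planted-recovery results bound correctness, not
  real-data robustness.
* The identity/coverage orthologue criterion misses orthologues conserved
  mainly at active-site residues (the geosmin-synthase situation); motif-
  aware clustering is out of scope.
* The shipped TF rule catalogue and β-ketoadipate KO defaults are starting
  points, not curated references.
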