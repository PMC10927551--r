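---
title: "Methods: simulating and detecting whole-genome duplications at chromosome scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and detecting whole-genome duplications at chromosome scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleokaryo)
```

## The problem

Whether two lineages share a whole-genome duplication (WGD) cannot be read
from gene counts alone: independent duplications, segmental duplications
and rampant rearrangement all mimic each other at that resolution. The
durable signal sits at chromosome scale. A WGD copies every chromosome at
once; afterwards the copies lose genes independently but from the *same*
ancestral complement, so descendant chromosomes of one ancestral chromosome
(AC) keep strongly overlapping gene sets for hundreds of millions of years.
This package implements that logic end to end: a simulator that generates
karyotype histories with complete ground truth, a reconstruction stage that
recovers ACs from cross-species homology, the overlapping-ratio (OR)
framework that turns retention overlap into ohnolog and ortholog calls, a
gene-tree classifier that places a test lineage's divergence relative to
one or two duplication rounds, and downstream classifiers for duplicate
expression fates and regulatory (ACR) genomic context.

All analyses are content-based: no sequences are simulated or aligned.
Genes are opaque tokens tagged with an ancestral family identifier, which
is exactly the information that survives into real ortholog tables.

## The simulator and what it emulates

A `genome_map` holds ordered genes on chromosomes; every chromosome carries
its descent record (source ACs, plus one subgenome letter per WGD), so
every downstream call can be checked against truth. The events are:

* **WGD** (`apply_wgd`), multiplicity 2 or 3. `mode = "allo"` adds an
  immediate extra loss round (default 15%) on one subgenome. This is a
  phenomenological stand-in for allopolyploidy: the biological evidence for
  an allopolyploid origin is retention *asymmetry* between subgenomes, and
  an asymmetric loss pulse reproduces that signature without modelling
  hybridization itself.
* **Fusion / fission** (`apply_fusion`, `apply_fission`), concatenation and
  breakpoint splitting with descent-record union/copy.
* **Attrition** (`apply_attrition`): per-gene loss, translocation to a
  uniformly chosen other chromosome, and small-scale duplication that stays
  on the donor chromosome half the time. The tandem bias is deliberate:
  without it, midpoint-split halves of one chromosome would share *no*
  families and the fission control would be trivially zero instead of a
  small positive background.
* **Speciation** (`speciate`): independent attrition per descendant;
  orthology truth is "same chromosome name".

Rates are per-gene probabilities in [0, 1]. The study conditions used
throughout the tests and the acceptance script are 300-gene ACs, 20–30%
per-copy loss, 1–2% translocation and 2–5% small-scale duplication; the
pre-1R chromosome number is 17 and a triplication follows a duplication in
the cyclostome-style history. Defaults that the sources leave open were
fixed once at values a comparative genomicist would consider mid-range for
post-WGD vertebrate genomes and are not tuned per analysis.

What the simulator does **not** emulate: sequence evolution and alignment
noise, selection on gene dosage (losses are independent and uniform),
rate heterogeneity across families, segmental duplications larger than one
gene, and programmed DNA elimination. Passing round-trip tests therefore
show that the inference machinery is correct and well-calibrated under
independent-loss dynamics, not that real data meet those assumptions.

Similarity hit tables (`emit_hit_table`) emit one Normal bit-score per
homologous cross-genome pair, reported reciprocally, with e-value the
deterministic monotone map `exp(-bitscore/2)` capped at 1 — only score
*ordering* matters to reciprocal-best-hit selection. Scores carry no
phylogenetic signal; nothing downstream assumes they do. Spurious hits are
emitted one-directionally at a configurable rate and are eliminated by the
reciprocity requirement.

## Ancestral-chromosome reconstruction

`reconstruct_ac` chains: reciprocal best hits (e-value ≤ 1e-6; ties broken
by e-value then subject id, so results are reproducible), a Pearson
chi-squared test per chromosome pair on the 2×2 table
`[[n_ab, n_a − n_ab], [n_b − n_ab, N − n_a − n_b + n_ab]]` with margins
counted over homologue pairs of one genome comparison, Fisher's exact test
whenever an expected cell drops below 5, Benjamini–Hochberg correction
across all tested pairs as one family, and an edge for every pair with
observed > expected and q < 0.05. The margin construction is this
package's explicit choice; the test statistics themselves come from
`stats::chisq.test`/`fisher.test`, never reimplemented.

AC groups are connected components of the ingroup-restricted homology
graph. Components are then validated against the outgroup linkage map
(unidirectional best hits with the outgroup as reference, enriched by the
same test): a component mixing several outgroup linkage groups — which
happens whenever an interim fusion bridges two ACs — is split, each member
following the linkage group it shares most genes with. Without this step,
any history containing fusions chains ACs together and the recovered count
collapses; with it, the full gnathostome-style simulation (17 ACs, 1R,
8 interim fusions, 2R, 30% loss) recovers exactly 17 groups.

Outgroup genes are anchored to ACs by two rules: (1) the gene's own
chromosome is the linkage group tied to AC X and it has a homologue among
X's genes; (2) at least 5 of its distinct ingroup homologues lie on X's
chromosomes and no other AC reaches that threshold. Rules pointing at
different ACs leave the gene unanchored (conflict logged) — agreement is
required because an anchored list contaminated across ACs biases every OR
downstream.

## The overlapping ratio

`retention_profile` is a binary vector over an AC's anchored gene list;
`overlapping_ratio` divides shared retained genes by the smaller retained
total. Properties asserted in the tests: range [0, 1], symmetry,
invariance to query gene order and to inflating a chromosome with non-AC
genes, and monotone decay of the expected ohnologous OR with loss rate.
Chromosomes retaining fewer than 20 anchored genes are excluded before the
pairwise matrix is built — below that the ratio's denominator is too small
to be meaningful.

Ohnologous pairs are called at OR > 0.15, strictly: the threshold is the
empirical ceiling of the fission control (midpoint `artificial_split`
halves classified against their own AC), which stays below 0.08 across
1,000 simulated split pairs at the default duplication/translocation rates.
"Mutually ohnologous" sets are reported both as connected components and
as maximal cliques; components are the headline view because a single
edge lost to stochastic attrition should not split a true copy set, and
component/clique discrepancies are logged rather than hidden. Per-AC
multiplicity is the largest component (one lone qualifying descendant
counts 1), which under a duplication-plus-triplication history with 20%
loss equals six for every AC — the diagnostic ceiling for a shared
triplication.

Ortholog assignment across two species examines the cross-species OR
block. A chromosome whose two best partners sit within 10% relative OR of
each other (both above threshold) is reported as an ambiguous 1:2/2:1 case
*before* mutual-best matching, because a mutual-best tie-break inside such
a near-tie would be arbitrary; mutual best pairs among the remaining
chromosomes become 1:1 calls. The 10% tolerance is a package choice — the
underlying ambiguity (secondary chromosome loss) has no sharp boundary.

Clustering uses `1 − OR` with `stats::hclust(method = "ward.D")`, i.e. the
classical Lance–Williams Ward update on raw, unsquared dissimilarities;
the tests pin the merge heights to an independent Lance–Williams
implementation. `1 − OR` is not guaranteed Euclidean, so height inversions
are possible; `ward_cluster` reports them via an attribute instead of
reordering.

## Gene-tree compatibility

`label_backbone` roots each tree on its outgroup, assigns reference leaves
to the four post-2R clades A–D by chromosome of origin, and verifies the
((A,B),(C,D)) backbone after pruning test leaves; trees failing
verification are flagged unusable and never partially scored. For each
maximal test-species clade, `classify_test_genes` reduces the tree to the
backbone plus that clade and inspects the clade's sister set: inside or
sister to a single 2R clade supports both rounds; sister to a whole 1R
pair supports only the first; anything outside the ingroup supports
neither — so 2R support implies 1R support by construction. Branch lengths
and support values are ignored; multifurcations are scored by the most
permissive reading (a complete backbone clade beside the test clade in a
polytomy counts as its sister) and flagged ambiguous. Per-tree calls are
the conservative conjunction over the tree's test clades.

`simulate_gene_trees` writes the true topology for a declared divergence
timing (before both rounds, between them, after both), which makes the
classifier exactly invertible on clean input — the zero-error round trips
in the tests are 100/0-type checks, not statistical ones — and degrades
gracefully under random NNI moves.

## Duplicate fates and regulatory context

Expression domains are tissues with TPM strictly above 5 after quantile
normalization (`limma::normalizeQuantiles`, ties averaged). For an
ohnologue pair with both domains non-empty: equal sets → redundancy; one
set strictly inside the other → specialization (strong when the narrow
copy covers < 40% of the broad copy's domains, else mild); otherwise each
copy has an exclusive tissue → subfunctionalization. The three fates
partition all non-empty pairs — the tests prove it by enumerating every
subset pair of a 4-tissue universe.

`simulate_expression` constructs domain sets realizing each requested fate
and emits bounded multiplicative noise that provably cannot cross the
TPM-5 threshold, so planted fates are exactly recoverable from the emitted
matrix; the round-trip tests assert recovery on that matrix. Quantile
normalization is validated separately: re-ranking against a pooled
reference can legitimately move near-threshold values when tissues differ
in their expressed fraction, which is a property of normalization, not a
classifier error.

ACR context uses strand-aware windows anchored at the TSS: promoter
[−1000, +500], proximal [−5000, +1000] minus promoter, exonic
(protein-coding exons) minus proximal, distal otherwise, with ≥ 1 bp
overlap and precedence in that order (via `GenomicRanges::promoters` and
interval overlap). Each ACR is assigned the gene with the nearest TSS
measured from the ACR midpoint — a deliberate, uncapped choice in the
absence of a sharper definition of a gene's cis-regulatory territory; ties
go to the lower coordinate so annotation is deterministic. BED input is
0-based half-open, GFF3 1-based closed; conversions are covered down to
length-1 intervals.

## Numerical and procedural choices

* Every stochastic routine takes an explicit seed; multi-step drivers
  derive per-stage sub-seeds from one master seed, so whole pipelines are
  byte-reproducible and stages stay reproducible individually.
* Deterministic tie-breaks throughout: RBH ties by e-value then subject
  id; linkage ties by linkage-group name; AC ids by sorted member order;
  nearest-TSS ties by coordinate.
* Empty chromosomes are retained (flagged) rather than pruned so descent
  records and truth tables stay addressable.
* Degenerate inputs are explicit: OR is an error when a profile retains
  zero genes; an OR matrix with fewer than two qualifying chromosomes is
  an empty flagged result, not an error; fate classification refuses
  empty domain sets (such pairs are excluded and logged upstream).
* The mirrored-fusion null draws two distinct chromosomes uniformly per
  fusion and lets products fuse again; a mirror is two events joining the
  two copies of the same two pre-1R chromosomes. Alternative nulls
  (fusions restricted to distinct ACs, conditioning on an observed
  configuration) would give different fractions; the implemented procedure
  is documented in `?simulate_post1R_fusion_null` and checked against
  exhaustive enumeration at small size.

## Problem sizes

The test suite and the acceptance script run at the scales the analyses
use: 300-gene ACs; 1,000 split pairs and 500 ohnologous pairs for the OR
calibration; the full 17-AC reconstruction at ~14,000 genes per descendant
genome; 16 ACs for the triplication ceiling; 100–300 trees, pairs or genes
for the classifier round trips. These sizes give stable stochastic
summaries (the quantities compared are minima/maxima over hundreds of
replicates) while keeping a complete run in the tens of seconds.

## Known limitations

Uniform independent loss makes recovered retention overlaps somewhat
cleaner than real genomes, where dosage-sensitive families are retained in
blocks; the OR thresholds were calibrated against the simulator's
background, and a practitioner applying them to empirical maps should
re-run the fission control on their own data. The allopolyploidy model
reproduces retention asymmetry but not homoeologous exchange. Gene trees
are transcribed from true histories, so tree-estimation error enters only
through the NNI knob. Ortholog assignment considers only the two-species
case the workflow needs.
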