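# paleokaryo

Chromosome-scale analysis of whole-genome duplication (WGD) in deep
vertebrate evolution, for comparative genomicists who want to test
polyploidy scenarios — how many duplication rounds, in which lineage, shared
or independent — from gene *content* rather than sequence. The package
covers the full workflow used to interrogate the early-vertebrate 1R/2R
rounds and the cyclostome-specific triplication: a ground-truthed karyotype
simulator, ancestral-chromosome (AC) reconstruction from cross-species
homology, the overlapping-ratio framework for calling ohnologous and
orthologous chromosomes, gene-tree compatibility classification for WGD
timing, and post-WGD duplicate expression-fate plus accessible-chromatin
(ACR) context annotation.

## The core statistic

For an ancestral chromosome with anchored gene list *G*, the **retention
profile** of a modern chromosome *c* is the binary vector
*r<sub>c</sub>* ∈ {0,1}<sup>|G|</sup> with
*r<sub>c,i</sub>* = 1 iff a homologue of ancestral gene *i* survives on *c*
(multiplicity ignored; gene order irrelevant). The **overlapping ratio**
between two chromosomes descending from the same AC is

    OR(a, b) = |r_a ∧ r_b| / min(|r_a|, |r_b|)  ∈ [0, 1]

— the shared retained genes over the smaller retained total, insensitive to
the size difference between the two chromosomes. Chromosomes produced by a
WGD share most of their retained complement (high OR); chromosomes produced
by fission plus background translocation do not (empirically OR ≤ 0.15, the
calling threshold, strict). Because post-WGD subgenomes diverge before
speciation, interspecific orthologous chromosomes show higher OR than
intraspecific ohnologous ones, which is what lets one separate a shared
polyploidy from two independent ones. Supporting stages: reciprocal best
hits at e-value ≤ 1e-6, Pearson chi-squared 2×2 enrichment per chromosome
pair (Fisher fallback when expected counts drop below 5) with
Benjamini–Hochberg control at q < 0.05, Ward ("ward.D") clustering of
1 − OR, and a rooted gene-tree classifier that scores each test-species
clade against the ((A,B),(C,D)) post-2R backbone.

## Worked example

Simulate three ancestral chromosomes of 300 genes through a duplication
followed by a triplication (six copies of everything), erode 20% of gene
copies, and ask the OR machinery how many mutually ohnologous descendants
each AC has:

```r
library(paleokaryo)
anc <- make_ancestral_genome(3, 300)
fams <- lapply(split(anc$genes$family_id, anc$genes$chromosome), unname)
g <- apply_wgd(apply_wgd(anc, 2), 3)          # 1R then a triplication
g <- apply_attrition(g, loss_rate = 0.2, seed = 1)
g
#> <genome_map> species 'ancestor': 18 chromosomes (0 empty), 4296 genes, 899 families
ors <- or_analysis(list(g), fams)
ors$multiplicity
#>      ancestor
#> AC01        6
#> AC02        6
#> AC03        6
round(ors$matrices$AC01$values[1:3, 1:3], 2)
#>                   ancestor:AC01.a.a ancestor:AC01.a.b ancestor:AC01.a.c
#> ancestor:AC01.a.a              1.00              0.81              0.83
#> ancestor:AC01.a.b              0.81              1.00              0.79
#> ancestor:AC01.a.c              0.83              0.79              1.00
call_ohnologues(ors$matrices$AC01)
#> <ohnolog_calls> 6 chromosomes, 15 edges (OR > 0.15), 1 set(s)
```

Every AC is recovered with exactly six mutually ohnologous descendants (the
planted copy number), pairwise ORs around 0.8 — far above the 0.15 fission
ceiling — and the six chromosomes form a single fully connected set.

## Analysis workflow

The numbered drivers under `analysis/` narrate the full study on simulated
data and write their tables under `results/`:

1. `01_simulate_karyotypes.R` — gnathostome-style (1R, 8 interim fusions,
   2R) and cyclostome-style (1R + triplication) histories with ground truth.
2. `02_reconstruct_ancestral_chromosomes.R` — RBH → enrichment → AC
   grouping → outgroup gene anchoring.
3. `03_overlapping_ratio.R` — ohnolog calling vs the fission control,
   per-AC multiplicity, ortholog assignment, Ward dendrograms, retention
   asymmetry of auto- vs allopolyploidy.
4. `04_tree_compatibility.R` — 1R/2R support fractions by true divergence
   timing, with and without topology error.
5. `05_ohnologue_fates.R` — expression-fate classification and ACR genomic
   context.
6. `06_fusion_null.R` — Monte-Carlo null for mirrored post-1R fusions.

Run any of them from the repository root after installing, e.g.
`Rscript analysis/03_overlapping_ratio.R`.

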