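# codomains

Detection of **coexpression domains (CODs)** — runs of neighbouring genes
whose expression profiles are mutually correlated across samples — together
with the analyses needed to characterise them: inter-domain co-regulation
statistics with randomization null models, RIDGE (Region of Increased Gene
Expression) detection, coincidence statistics against chromatin domains
(TADs / contact domains), and a Hi-C contact-profile stack relating spatial
proximity to coexpression. A seeded synthetic-data generator plants known
domain structure so every stage can be validated against ground truth.

The package is aimed at transcriptomics groups asking whether, and where,
the linear arrangement of genes carries co-regulation: bulk RNA-seq cohorts
(normal or tumour), with optional Hi-C matrices and TAD/contact-domain BED
files on the side.

## The method

Per chromosome, genes are sorted 5'→3' and the Pearson matrix
`C(i,j) = cor(expr(gᵢ), expr(gⱼ))` is computed across samples. For each
gene `i` the domain-calling statistic is the TopDom-style window average

    binsignal(i) = 1/w² · Σₗ Σₘ C(U(l), D(m)),
    U = {i−w+1,…,i},  D = {i+1,…,i+w},  w = 4

which is high inside domains and collapses at their boundaries. CODs are
runs of above-threshold binsignal (threshold 0.15) delimited on both sides
by statistically significant boundaries — below-threshold runs whose
flanking binsignal windows differ in a pooled-variance Student t-test
(four values a side, p < 0.05) — or by chromosome ends; domains with fewer
than 4 genes are discarded and one internal below-threshold gene is
tolerated. Companion statistics include average intra-/inter-COD
coexpression (|mean| ≥ 0.2 classifies a domain pair as strongly
co-regulated), 50-bin distance profiles, coordinate-inversion and
border-shift nulls, Mann-Whitney/Bonferroni distribution comparisons,
hypergeometric gene-set enrichment, Knight-Ruiz Hi-C balancing,
observed-over-expected and contact-profile correlation (connectivity), and
20-bin connectivity-versus-coexpression profiles.

## Worked example

Simulate a cohort with five planted 10-gene blocks (within-block Pearson
0.6, 100 samples), build the correlation matrix, and call domains with the
default configuration:

```r
library(codomains)

spec <- plantedBlockSpec(seed = 1)      # 86 genes, 5 blocks, 100 samples
sim  <- generateExpression(spec)
C    <- buildCoexpressionMatrix(sim$expr)[["chrS"]]
res  <- callCods(C, sim$annotation)
res$cods
#> DomainSet of kind COD with 5 domains on chrS | median width 820000 bp | median genes 9
```

Per-domain statistics (gene-rank span, size, average intra-COD
coexpression, boundary p-values):

```r
as.data.frame(S4Vectors::mcols(domainRanges(res$cods)))
#>   firstRank lastRank nGenes avgIntraCoexpression  pLeft  pRight
#> 1         7       16     10                0.581 0.0060 0.00730
#> 2        23       32     10                0.617 0.0073 0.00190
#> 3        40       48      9                0.523 0.0019 0.00410
#> 4        55       63      9                0.536 0.0041 0.00130
#> 5        72       79      8                0.568 0.0013 0.00054
```

All five planted blocks are recovered; every boundary lands within one gene
of the planted edge and the intra-COD averages sit near the planted 0.6:

```r
evaluateRecovery(res$cods, sim$truth, tolGenes = 1)$boundaryF1
#> [1] 1
```

`writeDomainsBed(res$cods, "cods.bed", sidecar = "cods.stats.tsv")` exports
BED plus the per-domain table. A command-line front end covering the whole
workflow (`call | stats | ridges | compare | hic | simulate`) ships in
`inst/scripts/codomains.R`.

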