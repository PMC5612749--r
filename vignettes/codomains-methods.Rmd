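---
title: "Detecting coexpression domains along chromosomes: methods and design"
author: "codomains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting coexpression domains along chromosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codomains)
library(GenomicRanges)
library(S4Vectors)
```

## The problem

Neighbouring genes on mammalian chromosomes are often transcribed in a
coordinated way: runs of adjacent genes whose expression levels rise and
fall together across individuals. `codomains` detects such runs —
*coexpression domains* (CODs) — from a genes x samples expression table,
and provides the companion analyses needed to characterise them: inter-domain
co-regulation statistics, randomization null models, detection of regions of
increased gene expression (RIDGEs), coincidence statistics against chromatin
domains (TADs, contact domains), and a Hi-C contact-profile stack that
relates spatial proximity to coexpression.

The input model is deliberately simple: expression values are nonnegative
RSEM-style normalized abundances used untransformed (a `log2(x + 1)` option
exists for robustness work); genes are sorted 5'->3' by start coordinate
within each chromosome, irrespective of strand; and every statistic is
computed per chromosome on the Pearson correlation matrix
`C(i, j) = cor(expr(g_i), expr(g_j))` with genes indexed by chromosomal
rank. Zero-variance genes are kept in the ordering (so ranks and domain
coordinates never shift) but masked out of every average.

## The binsignal statistic and the caller

For gene `i` with window `w` (default 4), binsignal is the mean of the
`w x w` block of correlations between the upstream window
`U = {i-w+1, ..., i}` and the downstream window `D = {i+1, ..., i+w}`:

$$\mathrm{binsignal}(i) = \frac{1}{w^2} \sum_{l=1}^{w}\sum_{m=1}^{w}
C(U_l, D_m).$$

Because `U` ends at gene `i` while `D` starts at `i + 1`, the block never
touches the matrix diagonal and the value measures coexpression *across the
junction* between genes `i` and `i + 1`. This junction reading matters for
boundary placement: the literal alternative ("a COD is a run of genes with
high binsignal") systematically drops the last gene of every domain, because
that gene's downstream window already lies in the background — a one-gene 3'
bias. Under the junction semantics a COD spanning genes `a..b` corresponds
to above-threshold junctions `a..b-1`, and recovered boundaries on planted
data are unbiased.

The caller (`callCods()`) proceeds in four steps:

1. classify each junction as above or below the threshold (default 0.15,
   a typical genome-wide average binsignal in normal-tissue cohorts;
   `threshold` is configurable, and recomputing the mean binsignal of the
   data at hand is the portable choice for other tissues);
2. segment the rank axis into above-threshold runs, merging runs separated
   by at most `maxInternalDip = 1` below-threshold junction (single dips
   inside a domain are tolerated; two consecutive ones are not);
3. test each below-threshold run for boundary significance with a
   two-sided pooled-variance Student t-test comparing the four binsignal
   values ending at a gene against the four following it (`tWindow = 4`
   regardless of `w`, matching the published four-versus-four test);
4. emit every above-threshold run flanked on both sides by a significant
   boundary or a chromosome end and spanning at least `minCodGenes = 4`
   genes, together with its average intra-COD coexpression and both
   boundary p-values.

### Where exactly is the boundary test evaluated?

The published description computes the t-test "for each gene i" but does
not say which gene inside a below-threshold run decides the run's
significance. This is a genuinely open design point, so the package exposes
it (`anchor`): `"min"` (the deepest dip), `"midpoint"`, or the default
`"any"` — the run is significant if the test passes at any of its genes (p
reported as the minimum). Two observations drove the default:

* At the dip minimum both t-test windows typically lie inside the flat
  low region between domains, so the test compares two equally low window
  means and is badly underpowered; on planted-block data the `"min"` anchor
  misses many true boundaries outright.
* Anchors are extended by one gene on the 5' side of the run. The windows
  `U` (which includes gene `i`) and `D` (which does not) are asymmetric:
  at the last gene of a run the downstream window cleanly contains the
  following domain's high values, but no in-run anchor gives the mirrored
  clean split for the *preceding* domain. Testing the gene immediately
  before the run restores the symmetry; without it, boundaries 3' of a
  domain failed at a measured ~30% rate while 5' boundaries almost never
  did.

Runs of 2–3 below-threshold genes are shorter than a reportable boundary
region ("larger than three genes") yet too long to sit inside a domain.
The package lets them *delimit* domains when significant
(`qualifyingRun = 2`) while reporting only runs of at least
`minBoundaryRun = 4` as boundary regions; `strictBoundaryLength = TRUE`
restores the stricter reading in which only 4+-gene runs delimit anything.

### Tunables at a glance

| parameter | default | units | meaning |
|---|---|---|---|
| `w` | 4 | genes | binsignal window; 3–6 give near-identical domains |
| `threshold` | 0.15 | correlation | junction classification cutoff |
| `alpha` | 0.05 | — | boundary t-test significance |
| `minCodGenes` | 4 | genes | smaller domains are discarded |
| `maxInternalDip` | 1 | genes | below-threshold dip tolerated inside a domain |
| `minBoundaryRun` | 4 | genes | minimum reported boundary region |
| `qualifyingRun` | 2 | genes | minimum delimiting run (see above) |
| `tWindow` | 4 | values | binsignal values per t-test side |

## Domain statistics and null models

`codCoexpressionSummary()` partitions all intra-chromosomal gene pairs into
three populations — both genes in the same COD (*intra*), in two different
CODs (*inter*), at least one gene outside every COD (*rest*) — and computes
per-COD-pair average inter-COD coexpression with midpoint distances.
A pair with |average| >= 0.2 is classified `positive`/`negative`
("strongly significant" co-regulation); `distanceBinnedCoexpression()`
produces the 50-bin equal-count distance profile. Distribution comparisons
use the two-sided Mann-Whitney test (exact for small untied samples, normal
approximation with tie correction otherwise) with Bonferroni adjustment
`p_adj = min(1, p * n_tests)`.

The primary null model is **coordinate inversion** (`invertDomains()`):
every interval `[s, e)` maps to `[L - e, L - s)`, flipping the chromosome
end-for-end. Domain sizes, inter-domain gaps, genomic context and local
gene density are preserved exactly while gene composition changes; applied
twice it is the identity. Gene membership of a randomized domain is
recomputed from gene midpoints. A second null shifts every border by
100 kb up- or downstream (`shiftDomains()`), clipping at chromosome ends.
Chromosome length defaults to the largest annotated gene end — the
inversion is an isometry for any length at least that large, and fixing
the convention keeps runs reproducible.

One degenerate corner worth knowing about: on a *palindromic* layout
(equal blocks, equal gaps, equal flanks) inversion maps domains onto
domains and the null is powerless by construction. Real chromosomes are
never palindromic; the package's own null-model demonstrations therefore
use irregular layouts (`plantedBlockSpec(gapGenes = c(4, 11, 6, 15), ...)`).

## RIDGEs

`callRidges()` reimplements the classic moving-median rule: per-gene mean
expression across samples; a 39-gene moving median (19 up, 19 down,
truncated at chromosome ends); RIDGEs are maximal runs of at least 10
consecutive genes whose moving median strictly exceeds twice the
genome-wide median (computed over all genes, not per chromosome). The
strict inequality and the genome-wide reference are both deliberate: a
uniformly expressed genome yields no RIDGEs, and calls are invariant to
global rescaling of the expression units.

## Domain comparison

Coincidence between domain sets uses three published rules, all inclusive
at their thresholds: length coincidence (some single domain of the other
set overlaps >= 80% of this domain's length — an asymmetric relation,
reported in both directions), boundary coincidence (any boundary of the
other set within 10% of this domain's size; in bp for COD-versus-TAD
comparisons, in gene ranks for normal-versus-cancer COD comparisons, both
units implemented since the two published comparisons use different ones),
and gene-composition coincidence (>= 80% of this domain's genes contained
in some domain of the other set). Genes are assigned to domains by midpoint
under the 0-based half-open convention (a midpoint exactly at the open end
is outside). Enrichment of gene categories uses the upper-tail
hypergeometric test; boundary-coincidence proportions are compared with the
Pearson chi-square test (no continuity correction by default).

## The Hi-C stack

Contact matrices (triplet text at a declared resolution, 100 kb default)
are balanced with the Knight–Ruiz algorithm — a Newton-type inner-outer
iteration with conjugate-gradient inner solves; when the Newton step stalls
(possible on small or sparse matrices) the package falls back to symmetric
Sinkhorn–Knopp alternating scaling. Convergence is declared when included
row sums equal a common constant within `tol = 1e-6`; all-zero (or, via
`minNonzero`, sparser) bins are excluded beforehand and propagate as `NA`.
The observed-over-expected transform divides each entry by the mean
balanced value at its genomic distance, so per-diagonal O/E means are 1 by
construction. The profile-correlation ("connectivity") matrix is the
Pearson correlation of O/E row pairs, dropping undefined entries pairwise
and excluding the two self-contact columns of each pair.

Genes map to 100 kb anchors by midpoint integer division; a gene pair's
connectivity is its anchor pair's profile correlation, with same-anchor
pairs assigned 1 by convention (identical profiles; configurable, since the
published description leaves this case open). The 20-bin
connectivity-versus-coexpression profile ranks pairs by connectivity and
cuts them into equal-count groups.

## The synthetic generator

`generateExpression()` uses a latent-factor model rather than a direct
covariance Cholesky: each planted block `b` has a per-sample factor `F_b`;
a coupled block pair `p` shares an extra factor `G_p`; a gene in block `b`
is

$$x = \sqrt{\rho_\mathrm{intra} - s_b}\,F_b +
\sum_{p \ni b} \sqrt{\rho_\mathrm{inter}^{(p)}}\,G_p +
\sqrt{1 - \rho_\mathrm{intra}}\,\varepsilon,$$

with `s_b` the summed shared variance. Expected pairwise correlations are
exactly `rho_intra` within a block, `rho_inter` across coupled blocks and 0
elsewhere; infeasible targets (`s_b > rho_intra`) error out. Values are
placed on a nonnegative RSEM-like scale by an affine map (mean 100, sd 10)
— a shift rather than truncation, so correlations stay exact; at these
defaults a negative draw is a > 8-sigma event. The factor construction
scales to `n_genes >> n_samples` cheaply and all randomness flows through
one explicit seed.

`generateHic()` emits Poisson counts with expectation
`depth * d^(-decay) * boost^[same compartment]` (`decay = 1`, `boost = 2`,
`depth = 100` at distance 1 bin): power-law distance decay plus a
compartment checkerboard aligned with the coupled block groups, which is
exactly the structure the O/E + profile-correlation stage assumes.

What the generator does *not* emulate: count-like mean–variance coupling
(negative binomial noise, library-size effects), copy-number artefacts,
gene-density variation, nested or hierarchical domains, and inter-chromosomal
structure. Passing tests therefore demonstrate correctness of the
algorithms under the stated correlation model, not robustness to every
property of real cohorts.

## Validation design and problem sizes

The package validates itself at sizes chosen to keep the full suite fast
while leaving no estimator data-starved:

* **Recovery**: 5 planted 10-gene blocks (`rho_intra = 0.6`), 6-gene gaps
  and flanks, 100 samples, 20 seeds. Mean boundary F1 at ±1-gene tolerance
  is 1.0 at the published caller defaults.
* **Null calibration**: 20 seeded 500-gene background chromosomes; mean
  false CODs per chromosome is 0.
* **Coupling**: a 5-cycle of coupled pairs at `rho_inter = 0.3` (each
  block carries 2 × 0.3 shared variance, exactly its `rho_intra`), so half
  of all inter-COD pairs are truly co-regulated — strong enough that the
  intra > inter > rest ordering is significant at any seed.
* **Hi-C**: 80 genes / 80 bins, two 2-block compartments. The 20-bin
  connectivity-coexpression curve is tested as non-decreasing *within three
  standard errors of each adjacent-bin step* plus a large overall rise:
  the population curve is flat within a compartment tier, so finite
  cohorts jitter adjacent bins by a few hundredths and literal
  monotonicity would test the noise, not the trend.

Numerical conventions: Pearson uses the sample (n−1) convention; means over
partially undefined sets drop `NA` entries and reduce the divisor, and a
fully undefined mean is `NA` with a warning, never silently 0; equal
constant groups compare at `p = 1`; ties in ranking and binning are
resolved by stable order; equal-count binning uses
`bin = ceiling(rank * nBins / n)`, whose counts differ by at most one.

## Known limitations

* The boundary t-test treats binsignal values as independent samples;
  they are in fact autocorrelated (adjacent windows share `w − 1` genes),
  so boundary p-values are calibrated for ranking and thresholding rather
  than as literal error rates — matching their published use.
* The caller is single-scale: no nested or hierarchical domains.
* TADs are consumed, never called; Hi-C analyses stop at the
  profile-correlation matrix (no eigenvector compartment labels).
* Inter-chromosomal coexpression and contacts are out of scope.
* With fewer than `2w + 1` genes on a chromosome the caller returns an
  empty set with a warning rather than attempting degenerate windows.
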