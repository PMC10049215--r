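---
title: "Methods: integrated methylome-transcriptome analysis of a staged series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated methylome-transcriptome analysis of a staged series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`methexpr` analyses a three-stage (p21/p28/p35), three-replicate WGBS +
RNA-seq design end to end. This vignette is the package's account of the
statistical models behind each stage, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the design choices
that were genuinely open.

## Methylation levels

The level of a CpG in one sample is the maximum-likelihood binomial
estimate `C / (C + T)` from the methylated (`C`) and unmethylated (`T`)
read counts of its cytosine report row. Sites with coverage `C + T < 5`
are discarded (`min_coverage`, reads; raising it can only shrink the site
set — a tested invariant). Analysis is restricted to CpG-context cytosines.
Strands of a symmetric CpG dinucleotide are kept as separate sites by
default; `merge_strands = TRUE` pools the pair's counts before filtering.
Both conventions are in routine use and the choice only matters at
marginal coverage.

Downstream summaries follow fixed conventions: 20 equal histogram bins on
[0,1] with level 1 in the last bin; site classes low (&le; 25%), medium
(25–75% exclusive), high (&ge; 75%) with closed outer boundaries; pairwise
sample correlations on sites defined in both samples of a pair (pairs with
fewer than two shared sites are flagged `NA`); PCA on complete-case sites
only, avoiding imputation.

## Feature annotation

`build_feature_index()` derives CGI shores (2 kb flanks) and shelves (the
next 2 kb), strand-aware promoters (default TSS &plusmn; 3 kb,
configurable via `promoter_up`/`promoter_down` because published
promoter-fraction figures are sensitive to the window), UTRs, exons,
introns, and gene bodies. Every position gets exactly one *primary* label
through the precedence CGI > shore > shelf > promoter > 5'UTR > 3'UTR >
exon > intron > gene body > distal intergenic; a fixed precedence makes
the label counts a partition, which the tests assert. Inputs are 1-based
inclusive; BED I/O converts at the boundary (0-based half-open). Nearest
genes get signed TSS distances (negative upstream in gene orientation);
exact ties resolve by gene-id order.

## DMR calling

The genome is tiled into non-overlapping 1 kb windows (the last partial
tile is kept). Within a tile, counts are pooled over sites and replicates
per stage group, and the 2x2 methylated/unmethylated-by-group table is
tested with a two-sided conditional exact test: summing hypergeometric
probabilities of outcomes no more likely than the observed one (the same
two-sided rule as `fisher.test`, matched in the tests to 1e-9 against a
brute-force enumeration). Pooling replicates treats within-group
biological variation as binomial; this is the standard small-n default and
the kernel is deliberately small and replaceable. BH correction is applied
across all tested tiles, records require |&Delta;meth| &ge; 0.25 and
q &le; 0.05 (both exposed), and adjacent significant same-direction tiles
are merged, with the merged record's means recomputed from pooled counts.
Tiles with fewer than `min_cpg = 3` sites covered in both groups are
skipped and counted. The window, cutoffs and minimum are conventional
choices, not derived quantities; all are arguments.

Null behaviour is assessed by zero-effect simulations: we report the mean
per-run false-discovery proportion (0/0 counted as 0), the quantity BH
controls. Pooling calls across runs would make the statistic degenerate
(any single call under a global null forces it to 1), so the per-run mean
is the meaningful calibration measure.

## Expression analysis

TPM is computed as `1e6 * (count/length) / sum(count/length)`; every
column sums to 1e6 by construction. Expressed genes reach TPM &ge; 0.5 in
at least one sample. The DEG kernel is a negative-binomial Wald test on
median-of-ratios-normalized counts: log2 fold change of group means with
pseudocount 0.5 (raw, unshrunken), and a per-gene method-of-moments
dispersion. With three replicates the raw gene-wise dispersion estimate is
far too noisy for a calibrated Wald test — null simulations during
development showed a plain normal reference rejecting at ~0.11, and a
t(4) reference, while calibrated, cannot produce the small p-values that
survive BH for genuinely strong effects. The kernel therefore moderates
the gene-wise estimate toward the across-gene mean dispersion
(`dispersion_shrink = 0.75` weight on the mean), restoring a raw type-I
error of ~0.05 at nominal 0.05 while keeping essentially full power at
4-fold changes. This mirrors the information sharing that the field's DEG
tools perform, in the simplest form that is fully specified and testable.
A DEG requires BH-adjusted p < 0.05 and |log2FC| &ge; 1.

Peak stages are the argmax of stage-mean TPM with ties going to the
earliest stage (flagged). Fuzzy c-means runs on z-standardized stage-mean
trajectories (three points per gene; zero-variance genes are excluded and
reported) with c = 6, fuzzifier m = 1.25 — a common choice for
standardized expression trajectories — k-means++-style seeded
initialization for determinism, convergence when the largest center shift
drops below 1e-6 or after 500 iterations. The alternating updates make the
objective non-increasing, which the tests assert per iteration.

## Integration

Metagene profiles use 20 upstream, 100 body and 20 downstream bins
(upstream/downstream bins fixed at 250 bp for a 5 kb flank; body bins at
length/100, so short genes get fractional spans), oriented 5' to 3' by
strand; a CpG overlapping several genes' spans contributes once per gene
context. Expression strata are rank-based tertiles of stage-mean TPM
(deterministic under ties). One upstream source text mentions "four
groups (high, medium, or low)" — an internal inconsistency; three strata
are implemented.

Promoter methylation is the pooled `sum(C)/sum(C+T)` over covered CpGs in
TSS &plusmn; 3 kb (coverage-weighted, robust to low-coverage sites; an
unweighted mean would up-weight noisy sites), undefined for samples with
fewer than `min_sites = 3` covered CpGs. Correlation uses all nine samples
as points by default — with n = 9 the PNG cutoff r < &minus;0.475
corresponds to a one-sided p of roughly 0.1 — with `unit = "stage_means"`
(n = 3) as the alternative, since the correlation unit is a genuinely open
choice. Expression is log2(TPM + 1) by default for variance stabilization.
The PNG cutoff is strict (r exactly at the cutoff is excluded); DM-DEGs
are the exact intersection of PNGs with the DEG union over successive
contrasts; their trajectories are cut into six clusters by average-linkage
hierarchical clustering on z-scored stage means, labels ordered by peak
stage for stable naming.

## The synthetic-data generator

The generator's defaults describe the study conditions used throughout
the tests: 2 chromosomes x 1 Mb, 2000 genes, 3 stages x 3 replicates,
Poisson(15) per-site coverage, baseline 6 CpG/kb (12/kb inside CGIs), 5%
CHG/CHH records, 20 planted DMRs (2 kb, effect 0.4, alternating hyper/hypo
and contrast), 150 planted DM-DEGs (promoter methylation moving 0.6 across
the series, expression log2FC 2 per stage step in the opposite direction),
and 150 additional stage-peaked DEGs at log2FC 2. True levels come from a
feature-conditioned beta mixture: heavily methylated background
(Beta(8,2), mean 0.8) versus hypomethylated CGIs and TSS-proximal cores
(beta with concentration 30 around a gene-specific mean between ~0.03 and
~0.33 that *decreases with the gene's expression rank*). The static
expression-methylation coupling gives metagene profiles their TSS dip
ordering; the mixture weights produce the bimodal level histogram (largest
bins below 10% and above 50%) and a genome-wide mean near 50–60%, with
most sites heavily methylated. Observed counts are binomial draws under
the true level; zero-coverage sites are emitted as 0/0 rows so the
coverage filter has work to do.

Two placement rules keep planted signals attributable on the deliberately
crowded miniature genome: planted DMRs avoid planted DM-DEG promoter
windows, and planted DM-DEG genes keep &ge; 4 kb TSS spacing so one gene's
planted promoter signal cannot dominate a neighbour's &plusmn;3 kb
window. Because DM-DEG promoters genuinely change methylation between
stages, DMR calls overlapping them are excluded from the DMR precision
denominator during recovery evaluation rather than being counted as false
positives (they are not in the planted-DMR list, but they are not false).

What the generator does *not* emulate: read-level artifacts (bisulfite
conversion error, mapping bias), replicate-level batch effects or
biological overdispersion of methylation beyond binomial sampling,
realistic gene and CGI size distributions (genes sit ~1 kb apart, so
promoter windows of neighbours overlap pervasively — feature-class
contrasts are therefore demonstrated on sparser configurations),
sequence-driven CpG placement, and isoform structure. Passing the planted
recovery tests shows the pipeline's inferential machinery is correct and
calibrated under its stated noise model, not that real tissue data would
yield comparable effect sizes or error rates.

## Problem sizes and numerical details

The test and acceptance runs use the default 2 Mb / 2000-gene instance
(~15,000 CpG sites including extra CGI density, nine samples; the full
pipeline runs in seconds), twenty zero-effect 250 kb instances for null
calibration (~250 tiles each), an exhaustive tile-test oracle sweep over
all 2x2 tables with total &le; 20 plus 500 random tables with margins
&le; 200, and a 3200-gene power/calibration simulation for the DEG
kernel. Other numerical conventions: equal-probability ties in the exact
test are grouped with the standard (1 + 1e-7) relative tolerance; fuzzy
memberships at a zero-distance center collapse to that center; degenerate
expression quartiles fall back to the "high" rule with a message; BH
q-values are monotone in p by construction and asserted so.

## Known limitations

Replicate pooling makes the DMR test anticonservative if within-group
biological variation exceeds binomial noise; a per-replicate
overdispersion correction behind the same `test_tile()` contract is the
natural extension. The DEG kernel's moderated dispersion assumes a shared
dispersion scale across genes — appropriate here, where the generator uses
one — and would under-serve strongly heterogeneous real data compared to
trend-fitted shrinkage. Correlation-based PNG calling at n = 9 has limited
specificity (~10% of null genes pass r < -0.475 by chance); intersecting
with DEGs is what keeps DM-DEG precision high, and the same caveat applies
to real-data use of the cutoff.
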