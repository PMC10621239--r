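---
title: "svpopkit: methods and statistical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{svpopkit: methods and statistical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical and algorithmic conventions behind
each stage of `svpopkit`. It is a methods reference, not a tutorial; the
README contains a worked end-to-end example. Code chunks are illustrative and
not evaluated when the vignette source is rendered.

## Coordinates and record model

All internal coordinates are **0-based, half-open**: a deletion of bases
101-200 (1-based inclusive, as a VCF reports it) is stored as
`start = 100, end = 200, length = 100`. VCF and tabular readers convert on
input; `write_merged_vcf()` converts back. Three record conventions follow
from this:

* **Insertions** are anchored as a 1-bp interval at the insertion point
  (`end = start + 1`) and carry the *inserted* length in `length`, so breakpoint
  and size tolerances apply to INS exactly as to interval types.
* **Translocations (TRA)** are one record holding both breakends
  (`chrom:start` and `mate_chrom:mate_pos`) and have no length. When reading
  VCFs, BND mate pairs are joined via `MATEID` or, failing that, reciprocal
  coordinates, and the lower-coordinate breakend becomes the primary record;
  unpaired breakends are dropped with a warning.
* Genotype tokens are `0/0`, `0/1`, `1/1`; `./.` maps to `NA`. A sample with
  call evidence but no genotype stays `NA`; a sample with *no* evidence for a
  merged SV is reference (`0`). This distinction matters downstream: kinship
  mean-imputes `NA`, while frequency estimates use observed alleles only.

## Ensemble merging

Merging runs in three stages, all parameterized by one validated
`sv_config()` object.

**1. Clustering.** Calls are grouped per `(chrom, svtype)` and clustered by
single-linkage transitive closure: two calls link when
`|start_1 - start_2| <= 10`, `|end_1 - end_2| <= 10`, and
`|length_1 - length_2| <= 10` bp. TRA calls link when *both* breakends are
within 10 bp (same mate chromosome), with no size test. Single linkage is
deliberate: callers jitter breakpoints independently, so two calls for the
same event can each sit within tolerance of a third without being within
tolerance of each other. The closure is computed by a union-find kernel in
C++ over candidate pairs found by a sorted sweep; the test suite verifies the
partition against a brute-force oracle on 1000 random call sets and confirms
it is invariant to input order.

**2. Per-sample caller support.** Within each cluster, a sample's calls are
kept only if at least 2 of the 3 callers reported the event *in that sample*
(`per_sample = TRUE`, the default). A cohort-wide alternative (any 2 callers
across the cohort) is available but inflates per-sample false positives,
because one caller's private artifact in sample A is rescued by a different
caller's artifact in sample B.

**3. Representative and genotypes.** Each surviving cluster becomes one SV
with **lower-median** breakpoints and length (the median for odd counts, the
lower of the two middle values for even counts — always an observed
coordinate, never an average of two). Per sample, the consensus genotype is
the most severe reported (`1/1 > 0/1 > 0/0`). Crucially, the cross-sample
merge reuses the *pre-consensus* cluster partition rather than re-clustering
the survivors: re-clustering can split a cluster whose jitter outliers were
removed, manufacturing duplicate SVs.

Interval SVs strictly larger than 10 Mb are then dropped (TRA exempt), and
`calibrate_against_reference()` reports one-to-one breakpoint agreement with
a curated call set over a tolerance sweep.

## Annotation

`classify_genic_context()` intersects SVs with gene models
(`GenomicRanges::findOverlaps`) and assigns, in precedence order: CDS,
exon (non-coding portion), intron, upstream/downstream flank
(2 kb, strand-aware), intergenic. Impact follows the usual severity ladder:
CDS-disrupting DEL/DUP/INV and frameshift INS are HIGH; in-frame CDS
insertions (length divisible by 3) are MODERATE; exonic non-CDS are LOW;
intronic/flanking/intergenic are MODIFIER. TRA records are annotated at both
breakends and take the more severe context.

## Frequency divergence

For each SV, carriers are compared between the two populations with a
two-sided Fisher exact test on the 2x2 allele-count table, implemented by
summation of `dhyper()` point probabilities no greater than the observed
table's probability times `(1 + 1e-7)`; a zero margin yields `p = 1`. The
tolerance factor is the standard guard against floating-point ties in the
hypergeometric mass; the test suite verifies exact agreement (within 1e-12)
with full enumeration of every 2x2 table with margins up to 30, and with
`stats::fisher.test` on the published incomplete-penetrance carrier table.

P-values are Benjamini-Hochberg adjusted (`stats::p.adjust(method = "BH")`;
plain BH rather than an empirical-null method because SV sets at this scale
are too small and too discrete to estimate a null proportion stably). An SV
is called divergent only under the joint rule `q < 1e-4` **and** frequency
fold-ratio `> 2` (a zero denominator gives an infinite ratio, which passes).
Two properties of this design are worth stating:

* **Discreteness.** The exact test is conservative: at 100 samples the
  realized null rejection fraction at nominal 0.05 is about 0.03, which is
  the *attained level* of the exact conditional test given the observed
  margins, not a miscalibration. The acceptance tests compare the realized
  fraction to that attained-level oracle rather than to the nominal level.
* Under a frequency-matched null, the joint rule yields zero divergent calls
  at cohort sizes of 100; the `q` threshold alone already guarantees this at
  these sample sizes, and the fold-ratio requirement additionally screens
  out large-cohort hits with trivial effect sizes.

`group_specific_svs()` partitions by presence/absence per group,
`enrichment_test()` is a hypergeometric enrichment of annotation categories
among divergent SVs, and `summarize_landscape()` bins divergence along the
genome.

## Population structure

`bn_kinship()` computes the standardized relationship matrix
\(K_{ij} = L^{-1} \sum_l (g_{il} - 2p_l)(g_{jl} - 2p_l) / (2 p_l (1 - p_l))\)
over polymorphic SVs, mean-imputing missing dosages. "Polymorphic" requires
both `0 < p < 1` *and* nonzero dosage variance — a constant all-heterozygous
marker has `p = 0.5` but carries no relatedness information and would
otherwise corrupt the denominator. PCA is an eigendecomposition of K with a
deterministic sign convention (largest-magnitude loading positive) and
eigenvalue-scaled scores. `ld_prune()` is a forward position-ordered scan
dropping any marker with `r^2 > 0.5` against a retained marker within 10 kb.

## Mixed-model association

`fit_null_model()` is EMMA-style REML for
\(y = X\beta + u + e,\ u \sim N(0, \sigma_g^2 K)\): the likelihood is profiled
over \(\delta = \sigma_e^2/\sigma_g^2\) via the eigendecomposition of
\(S K S\) (S the covariate projection), maximized on a log-spaced grid over
\(\delta \in [10^{-5}, 10^5]\) refined by `optimize()`. A flat likelihood
(no detectable genetic variance) degenerates cleanly to OLS
(\(h^2 = 0\)), which the tests pin against `lm()`. `emmax_scan()` then holds
the variance components fixed, rotates phenotype, covariates, and genotypes
by the eigenvectors of K, and computes per-marker generalized-least-squares
F-tests in a single vectorized pass; under an identity kinship this
reproduces per-marker `lm()` exactly. Significance is Bonferroni at
family-wise 0.05, and significant markers within 1 Mb are merged into
signals. Two calibration facts from the test suite: the null-model scan on a
structured two-population cohort yields uniformly distributed p-values
(Kolmogorov-Smirnov), and the \(h^2\) estimate at n = 100 is unbiased but
has substantial sampling variance (median ~0.47 over replicates at true 0.5,
interquartile spread of roughly ±0.15) — single-cohort \(h^2\) values should
be read accordingly.

## Read-depth presence/absence

`compute_window_ratios()` averages per-base depth (via run-length encodings
and `IRanges` views; missing positions count as zero) in 100-kb windows
stepped every 10 kb, normalized by the sample's genome-average depth.
`call_depth_deletions()` reports maximal runs of windows with ratio
*strictly below* 0.5. The raw run boundaries overshoot the true breakpoints
by up to a window width, so the caller also reports refined boundaries from
an explicit edge model: a window overlapping the deletion edge with deleted
fraction \(f\) has expected ratio \(f\hat c + (1-f)\,b\), where \(\hat c\) is
the depth plateau inside the deletion (mean of interior run windows) and
\(b\) is the background ratio. The threshold crossing therefore happens at
\(f = \varphi = (b - 0.5)/(b - \hat c)\), giving
`refined_start = run_start + window * (1 - phi) - step/2` (symmetrically for
the end). Two details matter: \(b\) is the per-chromosome *median* window
ratio, not 1 — the genome-average normalization includes the deletion
itself, so the background of an unaffected region sits above 1; and the
`step/2` term centers the estimate within the one-step grid uncertainty,
bounding the error at half a step plus plateau-estimation noise. Simulation
shows boundary errors within one 10-kb step in >99% of replicates at 20x
coverage.

**Limitation:** heterozygous deletion carriers have an expected ratio of
about `0.5 * b`, which sits near (and with the background inflation, above)
the strict 0.5 cutoff, so single-sample depth calling targets homozygous
events; heterozygotes are recovered through the breakpoint-caller arm of the
pipeline instead. `deletion_carrier_table()` classifies carriers by
reciprocal-overlap (>= 50%) agreement between depth calls and a target
region, producing the 2x2 carrier-by-phenotype table tested with
`fisher_exact_p()`.

## Synthetic cohorts

`simulate_cohort()` places SVs on a 2-kb grid across two 5-Mb chromosomes
(collisions impossible given merge tolerances of 10 bp), draws
population-specific allele frequencies by shifting a common logit-scale
frequency ±N(0, divergence)/2 per population, and draws genotypes as
binomial(2, freq). `simulate_caller_outputs()` emulates three callers with
per-caller sensitivity 0.9, breakpoint jitter SDs of 2, 3, and 5 bp, and a
5% single-caller false-call rate (false calls are private to one caller, so
2-of-3 consensus removes them). The cohort embeds a 600-kb deletion
(chr1:2.0-2.6 Mb) with group-specific allele frequencies for the depth arm,
and one mid-frequency causal SV with a 1-residual-SD effect for the
association arm. All generators are deterministic given their `seed`
argument. Defaults were chosen once, from published descriptions of caller
behavior and crop-cohort scales, and are not adjusted to test outcomes; the
acceptance suite in `tests/testthat/test-acceptance.R` states its pass
criteria (recovery >= 95%, zero false merged SVs, calibration within Monte
Carlo error of exact oracles, and so on) independently of those defaults.

## Reproducibility

`run_pipeline()` executes the full chain from caller outputs to reports,
writing TSVs with the configuration echoed in a comment header, and
`scripts/acceptance.R --seed <int> --out <path>` regenerates the headline
quantities as JSON. Every random step is seeded; identical seeds give
byte-identical outputs.
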