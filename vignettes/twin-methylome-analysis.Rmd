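---
title: "Methods: discordant-twin methylome analysis with twinDMP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discordant-twin methylome analysis with twinDMP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinDMP)
```

## The design and the model

`twinDMP` analyses DNA methylation microarray data from monozygotic twin
pairs in which one twin carries a phenotype (the *affected* twin) and the
cotwin does not. Because MZ twins share genotype, age, sex, and much of
their environment — and because each pair is processed on a single array,
so batch is shared within pair too — the within-pair difference

$$d_{ij} = \beta_i(\text{affected}_j) - \beta_i(\text{unaffected}_j)$$

at probe $i$ in pair $j$ is internally controlled for essentially every
classical confounder. All inferential machinery in the package works on
these paired differences or on the two within-group distributions.

### Summed-rank DMP prioritization

At realistic cohort sizes (the package's reference conditions are 18 pairs)
and beta-scale effects of 0.04–0.07, no probe survives Bonferroni
correction across ~450,000 tests, and the spatial correlation of
methylation makes genome-wide error control of individual CpGs a poor fit
anyway. The prioritization therefore combines two rankings computed over
all analysed probes:

* `p_rank`: ascending rank of the paired-*t* *p*-value;
* `effect_rank`: ascending rank of $-|\overline{d_i}|$, so the largest
  absolute mean difference gets rank 1.

`rank_sum = p_rank + effect_rank` orders the final list. Ties within
either component receive average ranks; ties in the sum are broken by
ascending *p*, then probe id, making the ordering fully deterministic.
Average-tie ranks are what make the package's ten-probe worked example
(printed, rounded statistics for ten probes) reproduce its published
positions 1–7 exactly; positions 8–10 of that table depend on unrounded
values and are not recoverable from the printed numbers, which the test
suite deliberately does not assert. Bonferroni and Benjamini–Hochberg
columns are attached for reference only.

The paired *t* statistic uses the $(n-1)$-denominator SD and a two-sided
Student-*t* tail on $n-1$ df. Degenerate probes (all differences equal)
are mapped to $t = 0, p = 1$ when the common difference is 0, and to the
smallest representable positive *p* (flagged `degenerate`) otherwise, so
downstream ranking never sees NaN.

### Variance heterogeneity

Two complementary views are provided. Per probe, a two-sided F test
compares the affected twins' variance with the cotwins' on
$(n-1, n-1)$ df. Globally, the two per-probe variance vectors — paired by
probe — are compared with a Wilcoxon signed-rank test (normal
approximation with tie and continuity corrections; at $10^4$–$10^5$ probes
the approximation is exact for practical purposes, and the test suite
checks it against exact enumeration at small $n$). A `rank_sum` (unpaired)
variant is exposed by flag because the pairing-unit reading of a
"comparison of distributions" is a genuine judgement call; the signed-rank
pairing by probe is the default. The headline descriptive summary is the
proportion of probes with F-test $p < .05$ whose variance is higher in the
affected group.

A genome-wide mean comparison (`meanMethylationTest`) is included as a
negative control: per-sample mean betas compared by a paired *t*. Group
differences are expected in individual probes and in variance, not in the
global mean.

### QC, normalization, betas

Sample filter first, then probe filter, both idempotent:

* sample retained iff its fraction of failed calls is **< 5%**;
* probe removed iff its fraction of samples with failed calls is **> 5%**
  *or* its fraction of samples with bead count `< 3` is **≥ 5%**.

A *failed call* is, by default, detection $p \ge .05$ — the conventional
array reading in which a small detection *p* means signal above
background. Published filter wordings sometimes read the other way around;
because the package cannot resolve that ambiguity for its users, the
direction is a configuration switch (`normConfig(failDirection =
"below")`) rather than a silent guess. Boundary semantics are fixed and
tested: a bead count of exactly 3 is acceptable; exactly 5% of samples
failing detection does not remove a probe (strict >), while the bead-count
fraction comparison is inclusive (≥).

Normalization follows the *dasen* idea — quantile normalization with type
I and type II probes in separate strata after equalizing their
backgrounds — in a deliberately transparent form: per sample and channel,
type I intensities are shifted by the difference of the two design types'
5th-percentile intensities (floored at 0), then each channel × type
stratum is quantile-normalized across samples (rank-matched column means,
average ranks for ties; delegated to `limma::normalizeQuantiles`). The
published dasen uses normal-exponential background intercepts instead of a
percentile shift; the percentile stand-in is documented, testable against
a brute-force oracle, and leaves the method's substance — stratified
between-sample quantile normalization — intact. Betas are
$M/(M+U+100)$; the offset 100 is the de facto Illumina constant.

SNP-control probes (tri-modal betas over common polymorphisms) never enter
DMP, variance or region statistics. They drive the monozygosity check:
betas below 0.2 / above 0.8 call homozygous genotypes, the middle band
heterozygous, and a pair passes when call concordance across SNP probes
reaches 0.9. The 0.9 pass threshold is a package choice (the concordance
of true MZ pairs is near 1; unrelated pairs with uniform genotypes sit
near 1/3), exposed as an argument.

### Regions and annotation

Region calling is a transparent gap-based clusterer: per chromosome,
position-sorted probes chain while consecutive gaps are ≤ 500 bp, and
chains of ≥ 3 probes become regions, tested by a paired *t* on per-pair
means of member-probe betas with BH correction across regions. This
deliberately replaces index-based region schemes tied to proprietary array
annotation; it is order-invariant and equals an $O(n^2)$ single-linkage
oracle in the test suite. Annotation assigns up to 2 nearest TSSs within
250 kb, with signed distances oriented by the gene's strand (positive =
downstream of the TSS), ties broken alphabetically.

### Discordant-pair selection

Longitudinal symptom scores (SMFQ, range 0–26) select pairs: a pair
qualifies when the absolute within-pair difference reaches the threshold
(default 6, inclusive — the cutoff value itself must qualify) on at least
2 waves, *and* the same twin scores higher on every qualifying wave.
Consistency-as-same-direction is the package's reading of "consistent
discordancy"; qualifying waves need not be consecutive.

## The synthetic-data generator

Because no public dataset accompanies the study design this package
targets, the generator is first-class, tested code, and its defaults *are*
the reference study conditions: 18 pairs (13 female, 5 male), 20,000
probes of which 65 are SNP controls and 72% are type II, 50 planted DMPs
at $|\Delta\beta| = 0.07$ with random sign, and affected-twin noise
variance inflated by $\lambda = 2$ at 10% of probes.

Per probe, a baseline is drawn from a 0.4/0.2/0.4 mixture of Beta(2,18),
Beta(5,5), Beta(18,2) — the canonical bimodal 450K beta distribution. On
the logit scale, each pair adds a shared effect $N(0, \tau^2)$ and each
twin adds noise $N(0, \sigma^2)$ (times $\lambda$ for the affected twin at
inflated probes). Planted effects are added on the *beta* scale and
clipped to [0.001, 0.999], so realized effects are directly comparable to
published $\Delta\beta$ columns; clipping means extreme-baseline probes
realize slightly less than the nominal effect, which the ground-truth
regression test accounts for. Intensities are $M = \mathrm{round}(\beta
T)$, $U = \mathrm{round}((1-\beta)T)$ with $T$ log-normal (median 3,000),
plus an additive background of 300 on type I probes so the normalization
stage has real work; detection failures ($p \sim U(0,1)$) occur at rate
0.002 and bead counts are $1 + \mathrm{Poisson}(13)$. Randomness is split
into per-stage sub-streams derived from one seed, so enlarging the probe
panel does not perturb phenotype draws.

**Calibration of $\tau$ and $\sigma$, and why it is delicate.** Two
requirements pull against each other. The generator must produce
pair-shared correlation (real twins are correlated), yet the per-probe F
test between the two groups should hold its nominal size under the null —
and shared pair effects correlate the two groups' variance estimates,
which makes the F ratio under-dispersed (conservative), while the
logit-normal-to-beta transform produces light-tailed group distributions
(anti-conservative). The defaults $\tau = 0.10$, $\sigma = 0.16$ were
fixed by a pilot grid at which these two finite-sample effects balance
(null F rejection within a few tenths of a percentage point of 5% at
18 + 18 samples) while a planted $\Delta\beta = 0.07$ remains clearly
detectable (paired-*t* *p* down to $10^{-4}$–$10^{-3}$ at the least
favourable mid-methylation probes, far smaller at the bimodal extremes)
and $\lambda = 2$ inflation is reliably flagged by the global signed-rank
test. These values were frozen after the pilot and are not adjusted per
analysis.

**What the generator does not emulate:** probe cross-hybridization,
cell-type heterogeneity, age or batch trends, and the spatial correlation
of methylation along the genome (probes are independent given the
manifest). Passing tests therefore demonstrate the *procedures* are
correct and calibrated under a clean generative model — not that real
cohort data meet these assumptions.

## Problem sizes and numerical choices

The test suite exercises the full reference scale (18 pairs × 20,000
probes) for calibration and recovery checks, and 200 simulated cohorts for
the variance-inflation detection rate; unit tests run on reduced panels of
a few hundred to a few thousand probes. Tolerances: statistic/oracle
agreements are asserted at $10^{-12}$; Monte-Carlo quantities use CLT or
binomial 99% bands at the simulated size. Degenerate inputs (zero
variances, all-zero differences, empty screens) are mapped to documented
sentinels rather than NaN, and each such branch is unit-tested.

## Known limitations

* The dasen-style background stage is a percentile alignment, not the
  published normal-exponential fit; systematic chemistry differences
  beyond a location shift (e.g. type II dye bias curvature) are out of
  scope, as is BMIQ-style distributional correction.
* Region calling is purely positional; island/shore context is not used.
* The replication test (`caseControlTest`) is a targeted Welch *t* on
  nominated probes and intentionally applies no multiplicity correction;
  it is not a genome-wide case-control EWAS.
* With 5 male vs 13 female pairs the sex-difference check has limited
  power; a null result there is reassurance, not proof of sex-neutrality.
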