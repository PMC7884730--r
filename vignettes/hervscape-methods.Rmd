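---
title: "Methods behind hervscape: hERV biomarkers, absolute deconvolution and genomic feature scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind hervscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hervscape)
```

hervscape implements a sequencing-based biomarker stack for stage II/III
colorectal tumor cohorts: a human endogenous retrovirus (hERV) expression
score (median.hERV), absolute immune-cell fraction deconvolution by
ν-support-vector regression, a read-length-shift microsatellite instability
(MSI) caller, somatic variant/TMB/CIN/MATH feature extraction with a
Lynch-syndrome rule and exact concordance statistics, and Kaplan–Meier /
Cox survival stratification by combined CD8/hERV and clinicopathological
subgroups. Because the patient-level data such analyses are usually run on
cannot ship with a package, every stage is paired with a synthetic-cohort
generator that reproduces the statistical structure the methods assume, so
all claims made by the test suite are claims about that generative model.

## hERV quantification

Counts are normalized to counts per million, `CPM = 1e6 * count / library
size`, where the library size is the total sequenced library, not the sum
over the hERV panel — hERVs are a small fraction of a whole-transcriptome
library and their CPMs must not be forced to sum to 10^6. The stage order
is fixed and load-bearing:

1. CPM;
2. noise floor: values strictly below 0.5 CPM are set to zero;
3. expression filter: panel transcripts whose median CPM across tumor
   samples is strictly below 0.1 are dropped;
4. median.hERV: the per-sample median CPM over the retained panel.

Flooring before filtering matches the order in which the procedure is
described; the alternative (filter on raw CPM medians) retains
low-amplitude transcripts whose floored values are all zero, which is why
the regression test pins the order. The median uses the midpoint-average
convention for even panels — the statistic's name depends on it.

Two-group structure is recovered by Ward (`ward.D2`) agglomerative
clustering on Euclidean distances over per-transcript z-scored
`log2(CPM + 1)` profiles, cut at k = 2; the cluster with the larger median
of median.hERV is labeled "high". Ward on z-scores is the standard choice
behind two-block expression heatmaps and is deterministic. Continuous
scores (median.hERV, CD8 fraction, age) are dichotomized at the top 30% of
the cohort distribution using the type-7 (linear-interpolation) quantile;
ties at the threshold are all labeled high so the rule is
order-independent.

Robustness of median.hERV is measured by drawing 80% of the retained panel
without replacement 100 times and correlating (Spearman) each subsample's
scores with the full-panel scores across samples.

## Absolute immune deconvolution

Signature genes per cell type (CD4, CD8, CD19) are genes expressed at
≥ 20 CPM in their own type and ≥ 5-fold above both the maximum across all
background tissues and the maximum across the other cell types, capped at
the top 100 by fold change. Each signature column is rescaled so its mean
over its own genes equals a common constant (100), and the per-type scale
factors are stored: the regression coefficient for a normalized column maps
back to an absolute RNA fraction by multiplying with its stored factor.

A mixture is fit by ν-SVR with a linear kernel over the signature genes,
trying ν ∈ {0.25, 0.5, 0.75} and keeping the lowest-RMSE solution;
negative coefficients are clamped to zero and fractions are *not*
renormalized to sum to one — reporting absolute rather than relative
fractions is the point of the design. Before fitting, the full mixture
profile is re-anchored to CPM (sum 10^6). This, rather than quantile
matching against the signature distribution, is what makes the result
invariant to overall library scaling: full quantile matching would map a
diluted pure-cell mixture back onto the signature's value distribution and
destroy exactly the absolute scale the method is supposed to preserve.
Numerically, signatures and mixture are jointly divided by
`scale_constant / 10` before the solver (coefficients are unchanged);
with cost 10 and tolerance 10^-6 the QP converges without hitting
iteration caps. When no support vectors remain (a mixture with no immune
content inside the ε-tube of the flat fit) the solution is taken as
w = 0, which is the true optimum of that degenerate case.

Validation is by titration: mixtures at fractions {0, 0.05, 0.1, 0.2,
0.4} with three replicates under multiplicative log-normal noise
(sd 0.1), scored as the squared Pearson correlation between predicted and
true fraction per cell type. The acceptance script reports the median R²
across the three cell types; the test suite additionally checks noise-free
exactness, a 0.01-step simplex grid-search oracle, monotonicity along
titrations, and scale invariance.

## MSI calling

Sites are noncoding mononucleotide homopolymers of 10–50 bases (inclusive),
minus an exclusion list. For each site the read-weighted mean repeat length
of the tumor histogram is compared with a "known range": reference mean
± 3 reference standard deviations. In paired mode the reference is the
matched normal; in baseline mode the per-sample mean lengths of a baseline
panel are pooled (their mean and SD form the range), and a single-sample
baseline degenerates exactly to paired mode. The mean ± k·SD rule is the
simplest statistic consistent with the "outside the known range" language;
k is exposed in the interface. Sites with fewer than 20 tumor or reference
reads are not assessed — the coverage gate is a configurable stand-in for
the unstated "lower coverage" exclusion.

The MSI score is the exact ratio of unstable to assessed sites; a tumor is
MSI-H when the score is ≥ 0.30 (paired WES mode) or ≥ 0.20 (baseline panel
mode). The PCR rule is separate: five mononucleotide markers (BAT-25,
BAT-26, NR-21, NR-24, MONO-27 — the panel's second marker is BAT-26 even
where source text repeats BAT-25), MSI-High iff two or more are altered;
pentanucleotide identity markers only trigger a sample-mismatch warning.

## Somatic features

High-confidence variants must satisfy all of: tumor VAF ≥ 0.05, tumor
depth ≥ 50, normal depth ≥ 20, tumor alt reads ≥ 5, VAF_normal/VAF_tumor
strictly < 0.2, and both-strand support. Rejections are attributed to the
first failing rule in that order, so per-rule counts sum to the number of
rejected records. TMB is retained mutations divided by the exonic
footprint in Mb. An arm is deleted/amplified when the fraction of its
genes with the corresponding call strictly exceeds 20%; the CIN burden is
the count of arm events, classified stable/medium/high at cohort tertiles
by default (explicit cut points accepted — the tertile default stands in
for unspecified cut points). MATH is `100 · 1.4826 · MAD(VAF) /
median(VAF)` with the scaled MAD of the original MATH definition.

The Lynch rule is a deliberate reconstruction of an NCCN-style flowchart:
LS-positive iff a pathogenic MMR-gene (MLH1/MSH2/MSH6/PMS2) variant sits
at germline-like tumor VAF (default window [0.3, 0.7]), unless the only
qualifying gene is MLH1 and BRAF V600E is present (sporadic MSI-H through
promoter hypermethylation). Its outputs are validated for internal
consistency and through the concordance machinery, not against an external
truth set. PPA/NPA use exact Clopper–Pearson intervals from beta
quantiles; for x = n the lower bound is `0.025^(1/n)`.

## Survival stratification

OS is the endpoint date minus diagnosis; RFS is endpoint minus surgery;
durations convert to months at 30.4375 days/month (the figure every
median-survival number depends on). WTS− is CD8-low AND hERV-high, both at
the cohort-level top-30% cut (per-cohort, not per-stage — the simpler
reading of an ambiguous convention); CP− is any of: top-30% age, stage
III, or right-sidedness. Kaplan–Meier estimates, log-rank tests and Cox
models (Efron tie handling, Wald intervals — R's defaults) come from the
survival package; medians are reported as NA when a curve never crosses
0.5, and a cohort with zero events yields a log-rank statistic of exactly
0. Enrichment between categorical labels uses the two-proportion test with
continuity correction, falling back to Fisher's exact test when any
observed or expected cell is below 5 (the observed-cell clause keeps
sparse 2×2 tables on the exact path even when expected counts sit exactly
at 5).

## The synthetic cohort

The generator draws, per configuration (all defaults in `sim_config()`):

- **Expression**: two latent sample clusters (default 50/50) of hERV
  log2-CPM means 1 and 5 — a 4 log2-fold separation, wide enough that
  two-cluster recovery is essentially deterministic at n = 60; a shared
  per-sample latent factor gives hERV loci pairwise correlation ≈ 0.8
  across samples (applied cohort-wide); 40 of 200 loci silent at ~0.01
  CPM to exercise the expression filter; counts are negative-binomial
  (dispersion 0.2) around the log-normal means; the library size is the
  simulated column sum plus a 9.4×10^6 inflation constant (nominal
  10^7 library), so hERV CPMs are a small fraction of the library.
- **Immune**: purified profiles with 30 planted markers per type
  (~300 CPM on-target, 2 CPM off-target over a shared baseline), CPM
  normalized; cohort CD8 fractions are Beta draws whose mean shifts from
  0.04 to 0.04 + 0.10·ρ with the hERV-high cluster (default coupling
  ρ = 0.6); mixtures follow the exact convex model with log-normal noise.
- **MSI**: per-read stutter N(0, 0.5) around the reference length;
  unstable sites move 75% of reads 3 bases shorter; per-site instability
  0.5 (MSI-H) vs 0.02 (MSS).
- **Variants**: clonal VAFs Beta-centred at purity/2 (purity 0.6),
  30% subclonal; Poisson depths; a configurable fraction of records
  crafted to violate exactly one filter rule; MSI-H samples hypermutated
  ×10; Lynch-positive MSI-H samples carry a pathogenic MMR variant at
  VAF ~0.5, sporadic MSI-H samples carry MLH1 + BRAF V600E.
- **Survival**: exponential proportional hazards (baseline mean
  40 months, HR 4.4 for WTS−), independent exponential censoring
  calibrated to a 30% censored fraction; relapse precedes death as a
  Beta(8,2) fraction of the OS time and shares the endpoint date in the
  clinical table.

Every stream consumes a deterministic child seed of the configuration
seed, so identical configurations give byte-identical bundles on disk.

What the generator does **not** emulate: read-level artifacts (alignment,
GC and mappability bias, stutter asymmetry), batch effects and platform
shift between mixtures and signatures, non-proportional hazards,
informative censoring, and correlation structure among background genes.
Passing tests therefore demonstrate correctness of the statistical
machinery under the stated generative model, not performance on real
cohorts.

## Problem sizes and numerical choices

The test suite runs at deliberately modest scales chosen to make every
stochastic claim stable under its fixed seeds: cohorts of 20–60 samples
(200 hERV loci) for expression tests, 50 samples × 200 sites at coverage
100 for MSI recovery, 100 log-rank replicates at n = 500 and 20 Cox
replicates per hazard ratio at n = 1000 for the survival claims, and a
0.01-step simplex enumeration for the deconvolution oracle. Tolerances:
solver 10^-6 (SVR), exact rational arithmetic asserted for MSI scores and
concordance counts, and analytic boundary cases (quantile type 7, strict
vs non-strict thresholds) tested at machine precision. Variant-filter
boundary fixtures use VAF pairs whose ratio is exactly representable in
binary floating point (0.05/0.25), so the strict-< rule is exercised at
the true boundary rather than one ULP away.
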