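# hervscape

Sequencing-based prognostic biomarkers for stage II/III colorectal cancer
cohorts, built around the observation that human endogenous retrovirus
(hERV) expression and CD8+ tumor-infiltrating lymphocytes jointly stratify
survival. The package implements, as tested and reusable components:

- **median.hERV** — per-sample median CPM over a filtered hERV transcript
  panel (`CPM = 10^6 · count / library size`; values `< 0.5` CPM floored to
  0; panel transcripts with median tumor CPM `< 0.1` removed), with a
  downsampling robustness study and two-cluster hierarchical subtyping;
- **absolute immune deconvolution** — ν-support-vector regression of a bulk
  profile on purified-cell signatures placed on a common scale; reported
  coefficients are absolute RNA fractions (no sum-to-one renormalization),
  validated by in-silico titration linearity (median R² across
  CD4/CD8/CD19);
- **an MSI caller** — a microsatellite site is unstable when its tumor
  read-length mean falls outside the reference mean ± 3 SD; the MSI score
  is `unstable / assessed`, thresholded at ≥ 0.30 (paired WES) or ≥ 0.20
  (baseline panel); plus the 5-marker PCR rule (≥ 2 altered ⇒ MSI-High);
- **somatic features** — the six-rule high-confidence variant filter
  (VAF_T ≥ 0.05, DP_T ≥ 50, DP_N ≥ 20, AD_T ≥ 5, VAF_N/VAF_T < 0.2, both
  strands), TMB per Mb, arm-level CIN (> 20% of an arm's genes), MATH
  (`100 · 1.4826 · MAD(VAF) / median(VAF)`), a Lynch-syndrome rule, and
  PPA/NPA with exact Clopper–Pearson intervals;
- **survival stratification** — OS/RFS from dated intervals (months =
  days/30.4375), top-30% dichotomization, the CD8−/hERV+ ("WTS−") and
  clinicopathological (CP±) subgroups, Kaplan–Meier/log-rank and Cox
  (Efron ties) fits, and categorical enrichment tests;
- **a synthetic-cohort generator** — produces every input above
  (counts, profiles, MSI histograms, VCF, CN calls, clinical table) with
  the latent structure the analyses assume, so the whole pipeline is
  testable without patient data.

See `vignettes/hervscape-methods.Rmd` for the modeling details and the
generator's assumptions.

## Worked example

```r
library(hervscape)

cfg    <- sim_config(seed = 1, n_samples = 60)
bundle <- simulate_cohort_bundle(cfg)
dir    <- file.path(tempdir(), "bundle")
write_bundle(bundle, dir)

report <- run_pipeline(run_config(dir, file.path(tempdir(), "run"), seed = 1))

report$herv$n_retained        # 160 of 200 panel transcripts expressed
report$msi$n_msih             # 30 of 60 samples MSI-H
report$survival$cox_wts
#>          term       hr ci_lower ci_upper            p converged
#> 1 wts_negTRUE 4.769715 2.135533 10.65317 0.0001386722      TRUE
report$survival$strata$wts$groups
#>   group  n events median_months
#> 1  WTS- 10      9          6.01
#> 2  WTS+ 50     40         19.61
```

The generator planted 40 silent hERV loci (all removed by the expression
filter), made half the cohort MSI-H, and gave the CD8-low/hERV-high
(WTS−) subgroup a true hazard ratio of 4.4; the pipeline recovers a Cox
HR of 4.8 (95% CI 2.1–10.7) with a clearly separated Kaplan–Meier median
(6.0 vs 19.6 months) at n = 60. Per-stage tables (`herv_scores.csv`,
`fractions.csv`, `msi_results.csv`, `features.csv`) and `report.json` are
written to the run directory. A thin CLI over the same functions is in
`inst/cli/hervscape.R` (`simulate` and `run` subcommands).

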