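#' Filter somatic variants to high confidence
#'
#' A record is retained only when all six conditions hold: tumor VAF >= 0.05,
#' tumor depth >= 50, normal depth >= 20, tumor alt reads >= 5, normal/tumor
#' VAF ratio strictly below 0.2, and support on both strands. Records with
#' tumor VAF of zero fail the VAF rule before the ratio is evaluated. Each
#' rejected record is attributed to the first rule it violates, in the order
#' above.
#'
#' @param variants data.frame with columns vaf_tumor, vaf_normal, dp_tumor,
#'   dp_normal, ad_tumor, both_strands (see [simulate_variants()]).
#' @param vaf_min,dp_tumor_min,dp_normal_min,ad_tumor_min,vaf_ratio_max
#'   Filter thresholds.
#' @return List with `retained` (the filtered data.frame), `rejected` and
#'   `rejections` (named integer vector of per-rule first-failure counts).
#' @export
filter_somatic <- function(variants, vaf_min = 0.05, dp_tumor_min = 50,
                           dp_normal_min = 20, ad_tumor_min = 5,
                           vaf_ratio_max = 0.2) {
  req <- c("vaf_tumor", "vaf_normal", "dp_tumor", "dp_normal", "ad_tumor",
           "both_strands")
  missing_cols <- setdiff(req, names(variants))
  if (length(missing_cols))
    stop_("variant table is missing fields: %s",
          paste(missing_cols, collapse = ", "))
  bad <- which(is.na(variants$vaf_tumor) | is.na(variants$dp_tumor) |
                 variants$vaf_tumor < 0 | variants$vaf_tumor > 1)
  if (length(bad)) stop_("malformed variant record at line %d", bad[1])

  rules <- cbind(
    vaf_tumor = variants$vaf_tumor >= vaf_min,
    dp_tumor = variants$dp_tumor >= dp_tumor_min,
    dp_normal = variants$dp_normal >= dp_normal_min,
    ad_tumor = variants$ad_tumor >= ad_tumor_min,
    vaf_ratio = variants$vaf_tumor > 0 &
      variants$vaf_normal / pmax(variants$vaf_tumor, .Machine$double.xmin) <
        vaf_ratio_max,
    both_strands = as.logical(variants$both_strands)
  )
  pass <- rowSums(rules) == ncol(rules)
  first_fail <- apply(!rules, 1, function(r) which(r)[1])
  rejections <- stats::setNames(integer(ncol(rules)), colnames(rules))
  tab <- table(factor(colnames(rules)[first_fail[!pass]],
                      levels = colnames(rules)))
  rejections[names(tab)] <- as.integer(tab)
  list(retained = variants[pass, , drop = FALSE],
       rejected = variants[!pass, , drop = FALSE],
       rejections = rejections)
}

#' Tumor mutational burden per megabase
#'
#' @param n_somatic Number of retained somatic mutations.
#' @param exonic_mb Exonic coverage in megabases (> 0).
#' @return Mutations per megabase.
#' @export
compute_tmb <- function(n_somatic, exonic_mb) {
  if (exonic_mb <= 0) stop_("exonic_mb must be > 0")
  n_somatic / exonic_mb
}

#' Arm-level deletion/amplification events
#'
#' An arm is called deleted (amplified) when the proportion of deleted
#' (amplified) genes on the arm strictly exceeds `event_fraction`.
#'
#' @param n_genes Total genes on the arm (> 0).
#' @param n_deleted,n_amplified Gene counts per event type.
#' @param event_fraction Event threshold (default 0.20, strict >).
#' @return List: p_del, p_amp, deleted, amplified.
#' @export
arm_events <- function(n_genes, n_deleted, n_amplified,
                       event_fraction = 0.20) {
  if (n_genes <= 0) stop_("arm has no genes")
  if (n_deleted + n_amplified > n_genes)
    stop_("event gene counts exceed genes on arm")
  p_del <- n_deleted / n_genes
  p_amp <- n_amplified / n_genes
  list(p_del = p_del, p_amp = p_amp,
       deleted = p_del > event_fraction,
       amplified = p_amp > event_fraction)
}

#' Chromosomal instability burden across arms
#'
#' Counts arm-level events per sample from a gene-level call table and
#' assigns a categorical CIN class by cohort tertiles of the event counts
#' (or explicit cut points).
#'
#' @param cn_calls data.frame: gene, arm, sample_id, call
#'   (del/neutral/amp).
#' @param event_fraction Arm-event threshold (default 0.20).
#' @param cuts Optional two increasing cut points `c(low, high)`; counts
#'   `<= low` are stable, `<= high` medium, else high. Default: cohort
#'   tertiles.
#' @return data.frame: sample_id, cin_count, cin_class (stable/medium/high).
#' @export
cin_burden <- function(cn_calls, event_fraction = 0.20, cuts = NULL) {
  samples <- unique(cn_calls$sample_id)
  counts <- vapply(samples, function(s) {
    d <- cn_calls[cn_calls$sample_id == s, ]
    ev <- vapply(split(d$call, d$arm), function(calls) {
      e <- arm_events(length(calls), sum(calls == "del"),
                      sum(calls == "amp"), event_fraction)
      e$deleted + e$amplified
    }, numeric(1))
    sum(ev)
  }, numeric(1))
  if (is.null(cuts))
    cuts <- stats::quantile(counts, c(1 / 3, 2 / 3), type = 7,
                            names = FALSE)
  cls <- ifelse(counts <= cuts[1], "stable",
                ifelse(counts <= cuts[2], "medium", "high"))
  data.frame(sample_id = samples, cin_count = as.integer(counts),
             cin_class = cls, stringsAsFactors = FALSE, row.names = NULL)
}

#' Mutant-allele tumor heterogeneity (MATH) score
#'
#' `MATH = 100 * 1.4826 * median(|VAF - median(VAF)|) / median(VAF)`, i.e.
#' 100 times the scaled median absolute deviation of the tumor VAFs of
#' retained somatic variants divided by their median.
#'
#' @param vafs Numeric vector of tumor VAFs (>= 3 values).
#' @return The MATH score.
#' @export
math_score <- function(vafs) {
  if (length(vafs) < 3) stop_("MATH requires at least 3 variants")
  med <- stats::median(vafs)
  if (med == 0) stop_("median VAF is zero; MATH undefined")
  100 * stats::mad(vafs, constant = 1.4826) / med
}

#' Lynch-syndrome classification from tumor-only sequencing
#'
#' A patient is LS-positive when a pathogenic variant in one of the
#' mismatch-repair genes (MLH1, MSH2, MSH6, PMS2) is present at
#' germline-like tumor VAF (within `vaf_window`), unless the only
#' qualifying gene is MLH1 and the tumor also carries BRAF V600E, which
#' marks sporadic MSI-H through MLH1 promoter hypermethylation.
#'
#' @param variants data.frame of one patient's variants with columns gene,
#'   pathogenic, vaf_tumor.
#' @param braf_v600e Logical: BRAF V600E present in the tumor.
#' @param msi Optional MSI label; carried through for reporting only.
#' @param vaf_window Germline-like VAF window (default `c(0.3, 0.7)`).
#' @return `"LS-positive"` or `"LS-negative"`.
#' @export
classify_lynch <- function(variants, braf_v600e, msi = NULL,
                           vaf_window = c(0.3, 0.7)) {
  req <- c("gene", "pathogenic", "vaf_tumor")
  missing_cols <- setdiff(req, names(variants))
  if (length(missing_cols))
    stop_("variant annotations missing fields: %s",
          paste(missing_cols, collapse = ", "))
  mmr <- c("MLH1", "MSH2", "MSH6", "PMS2")
  hit <- variants$gene %in% mmr & variants$pathogenic &
    variants$vaf_tumor >= vaf_window[1] & variants$vaf_tumor <= vaf_window[2]
  genes <- unique(variants$gene[hit])
  if (isTRUE(braf_v600e)) genes <- setdiff(genes, "MLH1")
  if (length(genes)) "LS-positive" else "LS-negative"
}

#' Positive/negative percent agreement with exact binomial intervals
#'
#' Treats `reference` as truth: PPA = TP / (TP + FN), NPA = TN / (TN + FP).
#' 95 percent confidence intervals are exact Clopper-Pearson intervals from
#' binomial tail inversion (beta quantiles); for x = n the lower bound is
#' `0.025^(1/n)` and the upper bound 1.
#'
#' @param test Logical vector of calls under evaluation (e.g. tumor-only).
#' @param reference Logical vector of reference calls (e.g. matched-normal
#'   confirmed), same length.
#' @param conf_level Confidence level (default 0.95).
#' @return List: tp, fp, fn, tn, ppa, npa, ppa_ci, npa_ci (proportions;
#'   `NA` when the reference has no positives / negatives).
#' @export
concordance <- function(test, reference, conf_level = 0.95) {
  if (length(test) != length(reference))
    stop_("call vectors must have equal length")
  tp <- sum(test & reference)
  fp <- sum(test & !reference)
  fn <- sum(!test & reference)
  tn <- sum(!test & !reference)
  ci <- function(x, n) {
    if (n == 0) return(c(NA_real_, NA_real_))
    a <- (1 - conf_level) / 2
    lower <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
    upper <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
    c(lower, upper)
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       ppa = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       npa = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       ppa_ci = ci(tp, tp + fn),
       npa_ci = ci(tn, tn + fp))
}
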