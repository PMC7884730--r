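#' Simulate somatic variant calls with tumor/normal support
#'
#' Draws per-sample somatic variant records carrying the fields the
#' high-confidence filter inspects: tumor and normal VAF and depth, tumor alt
#' read count and a both-strands flag. Clonal variants have VAFs centred on
#' `purity_mean / 2`, subclonal variants lower; depths are Poisson. A
#' configurable fraction of records is crafted to violate exactly one filter
#' rule each, so the filter's per-rule accounting is exercised. MSI-H samples
#' are hypermutated by `msih_variant_multiplier`. A subset of MSI-H samples
#' carries a pathogenic mismatch-repair (MMR) germline-like variant (Lynch
#' syndrome); the remaining MSI-H samples are sporadic and instead carry an
#' MLH1 pathogenic variant together with BRAF V600E.
#'
#' @param cfg A [sim_config()].
#' @param sample_ids Optional sample IDs (default `S001..`).
#' @param msi_status Optional "MSI-H"/"MSS" per sample; drawn if `NULL`.
#' @param violation_rate Fraction of records crafted to violate one filter
#'   rule.
#' @param lynch_fraction Fraction of MSI-H samples that are Lynch-positive.
#' @return List with `variants` (data.frame, one row per record, columns
#'   sample_id, chrom, pos, ref, alt, vaf_tumor, vaf_normal, dp_tumor,
#'   dp_normal, ad_tumor, both_strands, gene, pathogenic) and `truth`
#'   (per-record `passes_filter` flag, per-sample `ls_status` and
#'   `braf_v600e`).
#' @export
simulate_variants <- function(cfg, sample_ids = NULL, msi_status = NULL,
                              violation_rate = 0.1, lynch_fraction = 0.5) {
  validate_sim_config(cfg)
  set.seed(child_seed(cfg$seed, "variants"))
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(cfg$n_samples))
  ns <- length(sample_ids)
  if (is.null(msi_status)) {
    n_h <- round(cfg$msi_fraction_msih * ns)
    msi_status <- sample(rep(c("MSI-H", "MSS"), c(n_h, ns - n_h)))
  }
  names(msi_status) <- sample_ids

  mmr_genes <- c("MLH1", "MSH2", "MSH6", "PMS2")
  bases <- c("A", "C", "G", "T")
  rbeta_mean <- function(n, mean, conc) {
    stats::rbeta(n, mean * conc, (1 - mean) * conc)
  }

  msih <- msi_status == "MSI-H"
  ls_status <- stats::setNames(rep("LS-negative", ns), sample_ids)
  braf <- stats::setNames(rep(FALSE, ns), sample_ids)
  if (any(msih)) {
    idx_h <- which(msih)
    n_ls <- round(lynch_fraction * length(idx_h))
    ls_idx <- if (n_ls > 0) sample(idx_h, n_ls) else integer(0)
    ls_status[ls_idx] <- "LS-positive"
    braf[setdiff(idx_h, ls_idx)] <- TRUE   # sporadic MSI-H: MLH1 + BRAF
  }

  per_sample <- function(s) {
    lam <- cfg$n_variants_mean *
      if (msih[s]) cfg$msih_variant_multiplier else 1
    n <- stats::rpois(1, lam)
    if (n == 0L) return(NULL)
    clonal <- stats::runif(n) < 0.7
    vaf_target <- ifelse(clonal,
                         rbeta_mean(n, cfg$purity_mean / 2, 60),
                         rbeta_mean(n, cfg$purity_mean / 6, 60))
    dp_t <- stats::rpois(n, 150) + 50L
    dp_n <- stats::rpois(n, 80) + 25L
    ad_t <- stats::rbinom(n, dp_t, vaf_target)
    ad_t <- pmax(ad_t, 5L)
    vaf_t <- ad_t / dp_t
    vaf_n <- stats::rbinom(n, dp_n, 0.002) / dp_n
    both <- rep(TRUE, n)

    # craft single-rule violations on a random subset
    viol <- which(stats::runif(n) < violation_rate)
    for (i in viol) {
      rule <- sample(6L, 1)
      if (rule == 1L) {                    # tumor VAF < 0.05, AD still >= 5
        dp_t[i] <- 400L; ad_t[i] <- 14L; vaf_t[i] <- ad_t[i] / dp_t[i]
      } else if (rule == 2L) dp_t[i] <- 49L - stats::rbinom(1, 20, 0.5)
      else if (rule == 3L) dp_n[i] <- 19L - stats::rbinom(1, 10, 0.5)
      else if (rule == 4L) {               # AD < 5 but VAF kept >= 0.05
        dp_t[i] <- 60L; ad_t[i] <- 4L; vaf_t[i] <- ad_t[i] / dp_t[i]
      } else if (rule == 5L) vaf_n[i] <- 0.5 * vaf_t[i]
      else both[i] <- FALSE
    }
    if (any(ad_t > dp_t)) dp_t <- pmax(dp_t, ad_t)

    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    data.frame(sample_id = sample_ids[s],
               chrom = paste0("chr", sample(1:22, n, replace = TRUE)),
               pos = sample.int(1e8, n),
               ref = ref, alt = alt,
               vaf_tumor = vaf_t, vaf_normal = vaf_n,
               dp_tumor = dp_t, dp_normal = dp_n, ad_tumor = ad_t,
               both_strands = both,
               gene = "", pathogenic = FALSE,
               stringsAsFactors = FALSE)
  }

  tabs <- lapply(seq_len(ns), per_sample)

  # driver annotations: MMR germline-like variants and BRAF V600E
  extra <- lapply(seq_len(ns), function(s) {
    out <- NULL
    mk <- function(gene, vaf, pathogenic) {
      dp <- 200L
      data.frame(sample_id = sample_ids[s], chrom = "chr3",
                 pos = sample.int(1e8, 1), ref = "C", alt = "T",
                 vaf_tumor = vaf, vaf_normal = 0,
                 dp_tumor = dp, dp_normal = 100L,
                 ad_tumor = as.integer(round(vaf * dp)),
                 both_strands = TRUE, gene = gene, pathogenic = pathogenic,
                 stringsAsFactors = FALSE)
    }
    if (ls_status[s] == "LS-positive")
      out <- mk(sample(mmr_genes, 1), stats::runif(1, 0.4, 0.6), TRUE)
    if (braf[s])
      out <- rbind(out,
                   mk("MLH1", stats::runif(1, 0.4, 0.6), TRUE),
                   mk("BRAF", rbeta_mean(1, cfg$purity_mean / 2, 60), TRUE))
    out
  })

  variants <- do.call(rbind, c(tabs, extra))
  if (is.null(variants)) {
    variants <- data.frame(sample_id = character(), chrom = character(),
                           pos = integer(), ref = character(),
                           alt = character(), vaf_tumor = numeric(),
                           vaf_normal = numeric(), dp_tumor = integer(),
                           dp_normal = integer(), ad_tumor = integer(),
                           both_strands = logical(), gene = character(),
                           pathogenic = logical(), stringsAsFactors = FALSE)
  }
  variants <- variants[order(variants$sample_id, variants$chrom,
                             variants$pos), , drop = FALSE]
  rownames(variants) <- NULL
  passes <- with(variants, vaf_tumor >= 0.05 & dp_tumor >= 50 &
                   dp_normal >= 20 & ad_tumor >= 5 &
                   (vaf_tumor > 0 & vaf_normal / vaf_tumor < 0.2) &
                   both_strands)
  list(variants = variants,
       truth = list(passes_filter = passes, ls_status = ls_status,
                    braf_v600e = braf, msi_status = msi_status))
}

#' Simulate gene-level copy-number calls with arm-level events
#'
#' Assigns genes to chromosome arms and, per sample, marks a random subset of
#' arms as truly deleted or amplified; genes on an event arm receive the
#' corresponding call with probability `gene_event_rate`, genes elsewhere
#' with a small background rate, so that the arm-level >20 percent rule
#' recovers the planted events.
#'
#' @param cfg A [sim_config()].
#' @param sample_ids Optional sample IDs.
#' @param n_arms,genes_per_arm Catalog size.
#' @param arm_event_rate Per-arm probability of a true event per sample.
#' @param gene_event_rate Per-gene call rate on a true event arm.
#' @param background_rate Per-gene false call rate elsewhere.
#' @return List with `cn_calls` (data.frame: gene, arm, sample_id, call in
#'   del/neutral/amp) and `truth` (arms x samples character matrix of planted
#'   events).
#' @export
simulate_cn_calls <- function(cfg, sample_ids = NULL, n_arms = 10L,
                              genes_per_arm = 50L, arm_event_rate = 0.15,
                              gene_event_rate = 0.5,
                              background_rate = 0.02) {
  validate_sim_config(cfg)
  set.seed(child_seed(cfg$seed, "cn"))
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(cfg$n_samples))
  arms <- paste0(rep(1:ceiling(n_arms / 2), each = 2, length.out = n_arms),
                 rep(c("p", "q"), length.out = n_arms))
  genes <- sprintf("CN_GENE_%04d", seq_len(n_arms * genes_per_arm))
  gene_arm <- rep(arms, each = genes_per_arm)

  truth <- matrix("neutral", n_arms, length(sample_ids),
                  dimnames = list(arms, sample_ids))
  rows <- vector("list", length(sample_ids))
  for (s in seq_along(sample_ids)) {
    ev <- stats::runif(n_arms) < arm_event_rate
    kind <- ifelse(stats::runif(n_arms) < 0.5, "del", "amp")
    truth[ev, s] <- kind[ev]
    call <- rep("neutral", length(genes))
    for (a in seq_len(n_arms)) {
      idx <- which(gene_arm == arms[a])
      if (ev[a]) {
        hit <- stats::runif(length(idx)) < gene_event_rate
        call[idx[hit]] <- kind[a]
      } else {
        hit <- stats::runif(length(idx)) < background_rate
        call[idx[hit]] <- ifelse(stats::runif(sum(hit)) < 0.5, "del", "amp")
      }
    }
    rows[[s]] <- data.frame(gene = genes, arm = gene_arm,
                            sample_id = sample_ids[s], call = call,
                            stringsAsFactors = FALSE)
  }
  cn_calls <- do.call(rbind, rows)
  rownames(cn_calls) <- NULL
  list(cn_calls = cn_calls, truth = truth)
}
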