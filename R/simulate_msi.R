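#' Simulate microsatellite site catalog and read-length histograms
#'
#' Generates a catalog of noncoding mononucleotide homopolymer sites and, for
#' each tumor sample and its paired normal, a per-site histogram of observed
#' repeat lengths. Normal reads scatter symmetrically around the reference
#' repeat length (PCR stutter, sd `msi_stutter_sd`). In a stable tumor site
#' the tumor resamples the same distribution; in an unstable site a fraction
#' `msi_shift_fraction` of reads carries a `msi_shift_bases`-base deletion,
#' shifting mass to novel shorter lengths. Each sample is truly MSI-H with
#' probability `msi_fraction_msih`, and sites are unstable at rate
#' `msi_unstable_rate_msih` (MSI-H) or `msi_unstable_rate_mss` (MSS).
#'
#' @param cfg A [sim_config()].
#' @param sample_ids Optional character vector of sample IDs (defaults to
#'   `S001..`); its length overrides `cfg$n_samples`.
#' @param msi_status Optional precomputed "MSI-H"/"MSS" label per sample; if
#'   `NULL` it is drawn from `cfg$msi_fraction_msih`.
#' @return List with `sites` (catalog data.frame: site_id, chrom, start, end,
#'   repeat_unit, ref_repeat_length, noncoding), `histograms` (long
#'   data.frame: site_id, sample_id, tissue, length, count) and `truth`
#'   (per-sample status and the sites x samples logical instability matrix).
#' @export
simulate_msi_data <- function(cfg, sample_ids = NULL, msi_status = NULL) {
  validate_sim_config(cfg)
  if (cfg$msi_n_sites < 1L) stop_("invalid config: msi_n_sites must be >= 1")
  if (cfg$msi_coverage < 1L) stop_("invalid config: msi_coverage must be >= 1")
  set.seed(child_seed(cfg$seed, "msi"))
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(cfg$n_samples))
  ns <- length(sample_ids)
  n_sites <- cfg$msi_n_sites

  ref_len <- sample(10:30, n_sites, replace = TRUE)
  sites <- data.frame(
    site_id = sprintf("MS_%04d", seq_len(n_sites)),
    chrom = paste0("chr", sample(1:22, n_sites, replace = TRUE)),
    start = sort(sample.int(1e8, n_sites)),
    repeat_unit = sample(c("A", "T"), n_sites, replace = TRUE),
    ref_repeat_length = ref_len,
    noncoding = TRUE,
    stringsAsFactors = FALSE
  )
  sites$end <- sites$start + sites$ref_repeat_length

  if (is.null(msi_status)) {
    n_h <- round(cfg$msi_fraction_msih * ns)
    msi_status <- sample(rep(c("MSI-H", "MSS"), c(n_h, ns - n_h)))
  }
  names(msi_status) <- sample_ids

  draw_hist <- function(center, n_reads) {
    if (n_reads < 1L) return(integer(0))
    len <- pmax(1L, as.integer(round(center +
      stats::rnorm(n_reads, 0, cfg$msi_stutter_sd))))
    table(len)
  }

  unstable <- matrix(FALSE, n_sites, ns,
                     dimnames = list(sites$site_id, sample_ids))
  rows <- vector("list", n_sites * ns * 2L)
  k <- 0L
  for (s in seq_len(ns)) {
    rate <- if (msi_status[s] == "MSI-H") cfg$msi_unstable_rate_msih
            else cfg$msi_unstable_rate_mss
    uns <- stats::runif(n_sites) < rate
    unstable[, s] <- uns
    for (i in seq_len(n_sites)) {
      cov_n <- stats::rpois(1, cfg$msi_coverage)
      cov_t <- stats::rpois(1, cfg$msi_coverage)
      hn <- draw_hist(sites$ref_repeat_length[i], cov_n)
      if (uns[i]) {
        n_shift <- stats::rbinom(1, cov_t, cfg$msi_shift_fraction)
        ht_s <- draw_hist(sites$ref_repeat_length[i] - cfg$msi_shift_bases,
                          n_shift)
        ht_r <- draw_hist(sites$ref_repeat_length[i], cov_t - n_shift)
        ht <- c(ht_s, ht_r)
        ht <- tapply(as.integer(ht), names(ht), sum)
      } else {
        ht <- draw_hist(sites$ref_repeat_length[i], cov_t)
      }
      if (length(hn)) {
        k <- k + 1L
        rows[[k]] <- data.frame(site_id = sites$site_id[i],
                                sample_id = sample_ids[s], tissue = "normal",
                                length = as.integer(names(hn)),
                                count = as.integer(hn),
                                stringsAsFactors = FALSE)
      }
      if (length(ht)) {
        k <- k + 1L
        rows[[k]] <- data.frame(site_id = sites$site_id[i],
                                sample_id = sample_ids[s], tissue = "tumor",
                                length = as.integer(names(ht)),
                                count = as.integer(ht),
                                stringsAsFactors = FALSE)
      }
    }
  }
  histograms <- do.call(rbind, rows[seq_len(k)])
  rownames(histograms) <- NULL
  list(sites = sites[, c("site_id", "chrom", "start", "end", "repeat_unit",
                         "ref_repeat_length", "noncoding")],
       histograms = histograms,
       truth = list(msi_status = msi_status, unstable_sites = unstable))
}
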