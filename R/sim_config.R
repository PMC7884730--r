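#' Simulation configuration for a synthetic colorectal tumor cohort
#'
#' Bundles every knob of the synthetic-data generator. The defaults describe
#' the cohort structure the downstream analyses assume: two latent hERV
#' expression clusters separated by a 4-fold change in mean CPM, strong
#' co-expression among hERV loci within a patient, CD8+ infiltration coupled
#' to the hERV-high cluster, microsatellite sites that are unstable at a high
#' rate in MSI-H tumors and a low rate in MSS tumors, and proportional-hazards
#' survival with an elevated hazard in the CD8-/hERV+ (WTS-) subgroup.
#'
#' @param seed Integer seed; together with the other fields it fully
#'   determines every generated byte.
#' @param n_samples Number of tumor samples (>= 4).
#' @param n_herv Number of hERV loci on the reference panel (>= 2).
#' @param n_silent_herv How many of the `n_herv` loci are transcriptionally
#'   silent (near-zero CPM), exercising the expression filter.
#' @param n_background_genes Number of non-hERV background genes.
#' @param cluster_fraction_high Proportion of samples in the hERV-high cluster.
#' @param herv_logmean_low,herv_logmean_high Mean log2-CPM of expressed hERV
#'   loci in the low and high cluster. The defaults (1 and 5) put the
#'   clusters 4 log2-fold apart, a separation wide enough that two-cluster
#'   recovery is essentially deterministic.
#' @param herv_logsd Biological log2-CPM standard deviation per locus.
#' @param co_expression_rho Target pairwise correlation of hERV log-expression
#'   across samples, induced by a shared per-sample latent factor.
#' @param cd8_herv_rho Strength in `[0, 1]` of the coupling between the hERV
#'   cluster label and the mean CD8+ T-cell fraction.
#' @param dispersion Negative-binomial dispersion of counts around their
#'   log-normal means.
#' @param nominal_library Nominal library size used to convert design log-CPM
#'   into count means.
#' @param library_inflation Constant added to each sample's simulated column
#'   sum to form its library size, so that hERV plus background counts remain
#'   a small fraction of the library, as in real whole-transcriptome data.
#' @param msi_fraction_msih Proportion of samples that are truly MSI-H.
#' @param msi_unstable_rate_msih,msi_unstable_rate_mss Per-site probability
#'   that a microsatellite site is unstable in an MSI-H / MSS tumor.
#' @param msi_n_sites Number of microsatellite sites in the catalog.
#' @param msi_coverage Mean read coverage per site.
#' @param msi_shift_bases Deletion size (bases) at unstable sites.
#' @param msi_shift_fraction Fraction of tumor reads carrying the deletion at
#'   an unstable site.
#' @param msi_stutter_sd Standard deviation (bases) of PCR-stutter noise
#'   around the modal repeat length.
#' @param n_variants_mean Mean number of somatic variants per MSS sample
#'   (MSI-H samples receive `msih_variant_multiplier` times as many).
#' @param msih_variant_multiplier Hypermutator multiplier for MSI-H samples.
#' @param purity_mean Mean tumor purity used to centre clonal VAFs.
#' @param hazard_ratios Named numeric vector of hazard ratios per subgroup
#'   label, applied on top of a unit baseline hazard (all > 0).
#' @param baseline_scale Mean survival time (months) of the baseline group.
#' @param censoring_rate Expected proportion of administratively censored
#'   patients.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_samples = 60L,
                       n_herv = 200L,
                       n_silent_herv = 40L,
                       n_background_genes = 2000L,
                       cluster_fraction_high = 0.5,
                       herv_logmean_low = 1,
                       herv_logmean_high = 5,
                       herv_logsd = 0.5,
                       co_expression_rho = 0.8,
                       cd8_herv_rho = 0.6,
                       dispersion = 0.2,
                       nominal_library = 1e7,
                       library_inflation = 9.4e6,
                       msi_fraction_msih = 0.5,
                       msi_unstable_rate_msih = 0.5,
                       msi_unstable_rate_mss = 0.02,
                       msi_n_sites = 200L,
                       msi_coverage = 100L,
                       msi_shift_bases = 3L,
                       msi_shift_fraction = 0.75,
                       msi_stutter_sd = 0.5,
                       n_variants_mean = 60,
                       msih_variant_multiplier = 10,
                       purity_mean = 0.6,
                       hazard_ratios = c("WTS-" = 4.4),
                       baseline_scale = 40,
                       censoring_rate = 0.3) {
  cfg <- list(
    seed = as.integer(seed), n_samples = as.integer(n_samples),
    n_herv = as.integer(n_herv), n_silent_herv = as.integer(n_silent_herv),
    n_background_genes = as.integer(n_background_genes),
    cluster_fraction_high = cluster_fraction_high,
    herv_logmean_low = herv_logmean_low,
    herv_logmean_high = herv_logmean_high,
    herv_logsd = herv_logsd,
    co_expression_rho = co_expression_rho,
    cd8_herv_rho = cd8_herv_rho,
    dispersion = dispersion,
    nominal_library = nominal_library,
    library_inflation = library_inflation,
    msi_fraction_msih = msi_fraction_msih,
    msi_unstable_rate_msih = msi_unstable_rate_msih,
    msi_unstable_rate_mss = msi_unstable_rate_mss,
    msi_n_sites = as.integer(msi_n_sites),
    msi_coverage = as.integer(msi_coverage),
    msi_shift_bases = as.integer(msi_shift_bases),
    msi_shift_fraction = msi_shift_fraction,
    msi_stutter_sd = msi_stutter_sd,
    n_variants_mean = n_variants_mean,
    msih_variant_multiplier = msih_variant_multiplier,
    purity_mean = purity_mean,
    hazard_ratios = hazard_ratios,
    baseline_scale = baseline_scale,
    censoring_rate = censoring_rate
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (!is_count(cfg$seed)) stop_("invalid config: seed must be an integer")
  if (!is_count(cfg$n_samples, 4L))
    stop_("invalid config: n_samples must be an integer >= 4")
  if (!is_count(cfg$n_herv, 2L))
    stop_("invalid config: n_herv must be an integer >= 2")
  if (cfg$n_silent_herv < 0 || cfg$n_silent_herv >= cfg$n_herv)
    stop_("invalid config: n_silent_herv must be in [0, n_herv)")
  props <- c(cfg$cluster_fraction_high, cfg$co_expression_rho,
             cfg$cd8_herv_rho, cfg$msi_fraction_msih,
             cfg$msi_unstable_rate_msih, cfg$msi_unstable_rate_mss,
             cfg$msi_shift_fraction, cfg$censoring_rate)
  if (!is_prob(props))
    stop_("invalid config: all proportions must lie in [0, 1]")
  if (any(cfg$hazard_ratios <= 0))
    stop_("invalid config: hazard ratios must be > 0")
  if (cfg$dispersion <= 0) stop_("invalid config: dispersion must be > 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_samples, "samples,", x$n_herv, "hERV loci (",
      x$n_silent_herv, "silent ),", x$n_background_genes,
      "background genes, seed", x$seed, "\n")
  invisible(x)
}
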