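#' Simulate a complete synthetic cohort bundle
#'
#' Runs every generator under a single configuration and cross-links their
#' latent truths: the hERV cluster drives the mean CD8+ fraction, MSI status
#' drives hypermutation and the Lynch annotations, and the CD8-/hERV+ (WTS-)
#' subgroup receives its configured hazard ratio in the survival draw. The
#' returned bundle holds every input the analysis pipeline consumes plus all
#' latent labels.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `cohort_bundle`: counts, library_sizes,
#'   herv_panel, is_tumor, purified_profiles, background_profiles,
#'   immune_mixtures, true_fractions, msi_sites, msi_histograms, variants,
#'   cn_calls, clinical and `truth` (all latent labels).
#' @export
simulate_cohort_bundle <- function(cfg) {
  validate_sim_config(cfg)
  expr <- simulate_expression(cfg)
  sample_ids <- colnames(expr$counts)
  ns <- length(sample_ids)

  profiles <- simulate_immune_profiles(seed = cfg$seed)

  # immune fractions: CD8 mean shifts with the hERV cluster
  set.seed(child_seed(cfg$seed, "fractions"))
  high <- expr$truth$cluster == "high"
  cd8_mean <- 0.04 + 0.10 * cfg$cd8_herv_rho * high
  conc <- 80
  true_fractions <- cbind(
    CD4 = stats::rbeta(ns, 0.05 * conc, (1 - 0.05) * conc),
    CD8 = stats::rbeta(ns, cd8_mean * conc, (1 - cd8_mean) * conc),
    CD19 = stats::rbeta(ns, 0.02 * conc, (1 - 0.02) * conc)
  )
  rownames(true_fractions) <- sample_ids
  stopifnot(all(rowSums(true_fractions) <= 1))

  mix <- simulate_mixtures(profiles$purified, profiles$background[, 1],
                           true_fractions, noise_sd = 0.1,
                           seed = child_seed(cfg$seed, "cohort_mix"))
  colnames(mix$mixtures) <- sample_ids

  msi <- simulate_msi_data(cfg, sample_ids)
  vars <- simulate_variants(cfg, sample_ids,
                            msi_status = msi$truth$msi_status)
  cn <- simulate_cn_calls(cfg, sample_ids)

  # subgroup truth and survival
  cd8_high <- dichotomize_top_fraction(true_fractions[, "CD8"], 0.30)
  wts <- ifelse(!cd8_high & high, "WTS-", "WTS+")
  surv <- simulate_survival(wts, cfg$hazard_ratios, cfg$baseline_scale,
                            cfg$censoring_rate, seed = cfg$seed)

  set.seed(child_seed(cfg$seed, "clinical"))
  msih <- msi$truth$msi_status == "MSI-H"
  cms_pool <- function(is_h) {
    if (is_h) sample(c("CMS1", "CMS3", "CMS4"), 1, prob = c(0.6, 0.2, 0.2))
    else sample(c("CMS2", "CMS3", "CMS4"), 1, prob = c(0.5, 0.25, 0.25))
  }
  os_days <- pmax(2L, as.integer(round(surv$os_months * DAYS_PER_MONTH)))
  date_surgery <- pmin(as.integer(round(stats::runif(ns, 14, 45))),
                       os_days - 1L)
  clinical <- data.frame(
    id = sample_ids,
    age = pmin(pmax(as.integer(round(stats::rnorm(ns, 70, 8))), 40L), 92L),
    sex = sample(c("F", "M"), ns, replace = TRUE),
    stage = sample(c("II", "III"), ns, replace = TRUE, prob = c(0.6, 0.4)),
    sidedness = ifelse(msih,
                       ifelse(stats::runif(ns) < 0.7, "right", "left"),
                       ifelse(stats::runif(ns) < 0.35, "right", "left")),
    adjuvant = stats::runif(ns) < 0.4,
    date_diagnosis = 0L,
    date_surgery = date_surgery,
    date_endpoint = os_days,
    death_event = surv$os_event,
    relapse_event = surv$rfs_event,
    msi = msi$truth$msi_status,
    cms = vapply(msih, cms_pool, ""),
    stringsAsFactors = FALSE
  )

  structure(list(
    counts = expr$counts,
    library_sizes = expr$library_sizes,
    herv_panel = expr$herv_panel,
    is_tumor = expr$is_tumor,
    purified_profiles = profiles$purified,
    background_profiles = profiles$background,
    immune_mixtures = mix$mixtures,
    true_fractions = true_fractions,
    msi_sites = msi$sites,
    msi_histograms = msi$histograms,
    variants = vars$variants,
    cn_calls = cn$cn_calls,
    clinical = clinical,
    truth = list(
      cluster = expr$truth$cluster,
      silent = expr$truth$silent,
      marker_genes = profiles$truth_markers,
      msi_status = msi$truth$msi_status,
      unstable_sites = msi$truth$unstable_sites,
      passes_filter = vars$truth$passes_filter,
      ls_status = vars$truth$ls_status,
      braf_v600e = vars$truth$braf_v600e,
      cn_arm_events = cn$truth,
      cd8_high = cd8_high,
      wts_group = stats::setNames(wts, sample_ids)
    ),
    config = cfg
  ), class = "cohort_bundle")
}

#' Write a cohort bundle to plain-text files
#'
#' Emits every pipeline input into `out_dir`: counts.tsv,
#' library_sizes.tsv, herv_panel.txt, purified.tsv, background.tsv,
#' mixtures.tsv, variants.vcf (VCFv4.2), msi_sites.bed (0-based half-open),
#' msi_hist.tsv, cn_calls.tsv, clinical.csv, truth.yaml and manifest.yaml.
#' All files round-trip through [read_bundle()].
#'
#' @param bundle A `cohort_bundle` from [simulate_cohort_bundle()].
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop_("cannot create output directory '%s'", out_dir)
  p <- function(f) file.path(out_dir, f)

  write_tsv_matrix(bundle$counts, p("counts.tsv"), "transcript_id")
  utils::write.table(
    data.frame(sample_id = names(bundle$library_sizes),
               library_size = unname(bundle$library_sizes),
               is_tumor = as.integer(bundle$is_tumor)),
    p("library_sizes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(bundle$herv_panel, p("herv_panel.txt"))
  write_tsv_matrix(bundle$purified_profiles, p("purified.tsv"), "gene_id")
  write_tsv_matrix(bundle$background_profiles, p("background.tsv"), "gene_id")
  write_tsv_matrix(bundle$immune_mixtures, p("mixtures.tsv"), "gene_id")
  write_variants_vcf(bundle$variants, p("variants.vcf"))
  write_msi_sites_bed(bundle$msi_sites, p("msi_sites.bed"))
  utils::write.table(bundle$msi_histograms, p("msi_hist.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$cn_calls, p("cn_calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(bundle$clinical, p("clinical.csv"), row.names = FALSE,
                   quote = FALSE)

  truth <- bundle$truth
  yaml::write_yaml(list(
    cluster = as.list(truth$cluster),
    silent = names(truth$silent)[truth$silent],
    msi_status = as.list(truth$msi_status),
    ls_status = as.list(truth$ls_status),
    wts_group = as.list(truth$wts_group),
    marker_genes = truth$marker_genes
  ), p("truth.yaml"))
  yaml::write_yaml(c(unclass(bundle$config),
                     list(package_version =
                            as.character(utils::packageVersion("hervscape")))),
                   p("manifest.yaml"))
  invisible(out_dir)
}

#' Read a cohort bundle back from a directory
#'
#' @param dir Directory previously populated by [write_bundle()].
#' @return A list mirroring the writable parts of the bundle, plus the truth
#'   labels reloaded from `truth.yaml`.
#' @export
read_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  libs <- utils::read.delim(p("library_sizes.tsv"),
                            stringsAsFactors = FALSE)
  truth <- yaml::read_yaml(p("truth.yaml"))
  list(
    counts = read_tsv_matrix(p("counts.tsv")),
    library_sizes = stats::setNames(libs$library_size, libs$sample_id),
    is_tumor = stats::setNames(libs$is_tumor == 1L, libs$sample_id),
    herv_panel = readLines(p("herv_panel.txt")),
    purified_profiles = read_tsv_matrix(p("purified.tsv")),
    background_profiles = read_tsv_matrix(p("background.tsv")),
    immune_mixtures = read_tsv_matrix(p("mixtures.tsv")),
    msi_sites = read_msi_sites_bed(p("msi_sites.bed")),
    msi_histograms = utils::read.delim(p("msi_hist.tsv"),
                                       stringsAsFactors = FALSE),
    variants = read_variants_vcf(p("variants.vcf")),
    cn_calls = utils::read.delim(p("cn_calls.tsv"),
                                 stringsAsFactors = FALSE),
    clinical = utils::read.csv(p("clinical.csv"),
                               stringsAsFactors = FALSE),
    truth = list(
      cluster = unlist(truth$cluster),
      silent = unlist(truth$silent),
      msi_status = unlist(truth$msi_status),
      ls_status = unlist(truth$ls_status),
      wts_group = unlist(truth$wts_group),
      marker_genes = lapply(truth$marker_genes, unlist)
    ),
    manifest = yaml::read_yaml(p("manifest.yaml"))
  )
}
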