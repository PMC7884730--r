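#' Pipeline run configuration
#'
#' Collects every tunable constant of the analysis stages with the defaults
#' the package documents: noise floor 0.5 CPM, expression-filter median
#' 0.1 CPM, top fraction 0.30, MSI thresholds 0.30 (paired WES) / 0.20
#' (baseline panel), arm-event fraction 0.20 and the somatic filter
#' thresholds. Stage toggles allow partial runs.
#'
#' @param bundle_dir Directory holding the input bundle (see
#'   [write_bundle()]).
#' @param out_dir Directory for stage outputs and the report.
#' @param seed Integer seed for stochastic stages (downsampling study).
#' @param noise_floor,median_floor,top_fraction hERV stage constants.
#' @param msi_mode,msi_min_reads,msi_k_sd MSI stage settings.
#' @param exonic_mb Exonic footprint (Mb) for TMB.
#' @param arm_event_fraction Arm-level event threshold.
#' @param stages Named logical vector toggling `herv`, `deconv`, `msi`,
#'   `genomics`, `survival`.
#' @return A `run_config` list.
#' @export
run_config <- function(bundle_dir, out_dir = tempfile("hervscape_run_"),
                       seed = 1L,
                       noise_floor = 0.5, median_floor = 0.1,
                       top_fraction = 0.30,
                       msi_mode = "paired_wes", msi_min_reads = 20L,
                       msi_k_sd = 3, exonic_mb = 30,
                       arm_event_fraction = 0.20,
                       stages = c(herv = TRUE, deconv = TRUE, msi = TRUE,
                                  genomics = TRUE, survival = TRUE)) {
  structure(list(bundle_dir = bundle_dir, out_dir = out_dir,
                 seed = as.integer(seed),
                 noise_floor = noise_floor, median_floor = median_floor,
                 top_fraction = top_fraction, msi_mode = msi_mode,
                 msi_min_reads = msi_min_reads, msi_k_sd = msi_k_sd,
                 exonic_mb = exonic_mb,
                 arm_event_fraction = arm_event_fraction,
                 stages = stages),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' CLI flags and function arguments override file values; the file format
#' round-trips losslessly through [save_run_config()].
#'
#' @param path YAML file.
#' @param ... Overrides passed to [run_config()].
#' @return A `run_config`.
#' @export
load_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$stages)) y$stages <- unlist(y$stages)
  over <- list(...)
  y[names(over)] <- over
  do.call(run_config, y)
}

#' Save a run configuration to YAML
#' @param config A `run_config`.
#' @param path Output YAML file.
#' @export
save_run_config <- function(config, path) {
  x <- unclass(config)
  x$stages <- as.list(x$stages)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Run the full analysis pipeline on a bundle directory
#'
#' Stages run in fixed order (hERV quantification, deconvolution, MSI,
#' genomic features, survival stratification), each writing its tabular
#' output under `out_dir`, and the run ends with a single `report.json`
#' aggregating per-sample labels and the survival fits. Disabling the
#' deconvolution stage makes the survival strata fall back to hERV-only
#' grouping with an explicit warning.
#'
#' @param config A [run_config()].
#' @return The report, invisibly (a nested list; also written as JSON).
#' @export
run_pipeline <- function(config) {
  if (!dir.exists(config$bundle_dir))
    stop_("stage input: bundle directory '%s' does not exist",
          config$bundle_dir)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  b <- read_bundle(config$bundle_dir)
  p <- function(f) file.path(config$out_dir, f)
  report <- list(schema_version = "1.0",
                 parameters = unclass(config)[
                   c("seed", "noise_floor", "median_floor", "top_fraction",
                     "msi_mode", "msi_min_reads", "msi_k_sd", "exonic_mb",
                     "arm_event_fraction")])
  on <- function(stage) isTRUE(config$stages[[stage]])

  herv <- NULL
  if (on("herv")) {
    herv <- tryCatch(
      herv_quantify(b$counts, b$library_sizes, b$herv_panel, b$is_tumor,
                    config$noise_floor, config$median_floor,
                    config$top_fraction),
      error = function(e) stop_("stage herv: %s", conditionMessage(e)))
    utils::write.csv(herv$scores, p("herv_scores.csv"), row.names = FALSE)
    report$herv <- list(n_reference = attr(herv$panel, "n_reference"),
                        n_retained = attr(herv$panel, "n_retained"))
  }

  fractions <- NULL
  if (on("deconv")) {
    fractions <- tryCatch({
      sig <- build_signatures(b$purified_profiles, b$background_profiles)
      deconvolve_matrix(b$immune_mixtures, sig)
    }, error = function(e) stop_("stage deconv: %s", conditionMessage(e)))
    utils::write.csv(fractions, p("fractions.csv"), row.names = FALSE)
    report$deconv <- list(n_samples = nrow(fractions),
                          mean_cd8 = mean(fractions$CD8))
  }

  if (on("msi")) {
    msi <- tryCatch({
      sites <- filter_site_catalog(b$msi_sites)
      call_msi(sites, b$msi_histograms, config$msi_mode,
               min_reads = config$msi_min_reads, k_sd = config$msi_k_sd)
    }, error = function(e) stop_("stage msi: %s", conditionMessage(e)))
    utils::write.csv(msi, p("msi_results.csv"), row.names = FALSE)
    report$msi <- list(n_msih = sum(msi$classification == "MSI-H"),
                       n_samples = nrow(msi))
  } else msi <- NULL

  features <- NULL
  if (on("genomics")) {
    features <- tryCatch({
      cin <- cin_burden(b$cn_calls, config$arm_event_fraction)
      ids <- unique(b$clinical$id)
      per <- lapply(ids, function(s) {
        v <- b$variants[b$variants$sample_id == s, , drop = FALSE]
        f <- filter_somatic(v)
        tmb <- compute_tmb(nrow(f$retained), config$exonic_mb)
        math <- if (nrow(f$retained) >= 3 &&
                    stats::median(f$retained$vaf_tumor) > 0)
          math_score(f$retained$vaf_tumor) else NA_real_
        braf <- any(v$gene == "BRAF" & v$pathogenic)
        ls <- classify_lynch(f$retained, braf)
        data.frame(sample_id = s, tmb = tmb, math = math, ls_status = ls,
                   stringsAsFactors = FALSE)
      })
      merge(do.call(rbind, per), cin, by = "sample_id")
    }, error = function(e) stop_("stage genomics: %s", conditionMessage(e)))
    utils::write.csv(features, p("features.csv"), row.names = FALSE)
    report$genomics <- list(mean_tmb = mean(features$tmb),
                            n_ls = sum(features$ls_status == "LS-positive"))
  }

  if (on("survival")) {
    surv <- tryCatch({
      st <- compute_survival_times(b$clinical)
      if (!is.null(herv)) {
        mh <- herv$scores$median_herv[match(st$id, herv$scores$sample_id)]
      } else stop_("survival stratification requires the herv stage")
      if (!is.null(fractions)) {
        cd8 <- fractions$CD8[match(st$id, fractions$sample_id)]
        wts <- assign_wts_group(cd8, mh, config$top_fraction)$wts_group
      } else {
        warning("deconvolution disabled; falling back to hERV-only grouping")
        wts <- ifelse(dichotomize_top_fraction(mh, config$top_fraction),
                      "hERV+", "hERV-")
      }
      cp <- assign_cp_group(b$clinical$age, b$clinical$stage,
                            b$clinical$sidedness, config$top_fraction)
      fit_stratum <- function(g) {
        if (length(unique(g[!is.na(g)])) < 2) return(NULL)
        ok <- !is.na(g)
        k <- km_logrank(st$os_months[ok], st$os_event[ok], g[ok])
        list(groups = k$table, logrank_stat = k$logrank_stat,
             logrank_p = k$logrank_p)
      }
      cox <- cox_fit(st$os_months, st$os_event,
                     data.frame(wts_neg = wts %in% c("WTS-", "hERV+")),
                     mode = "univariate")
      list(strata = list(wts = fit_stratum(wts), cp = fit_stratum(cp),
                         msi = fit_stratum(b$clinical$msi)),
           cox_wts = cox, wts_table = as.list(table(wts)))
    }, error = function(e) stop_("stage survival: %s", conditionMessage(e)))
    report$survival <- surv
  }

  jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(report)
}
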