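#' Simulate a two-cluster hERV expression count matrix
#'
#' Draws counts for `n_herv` hERV loci plus `n_background_genes` unrelated
#' genes over `n_samples` tumor samples. Samples fall into two latent
#' clusters ("high" / "low" hERV expression) separated by
#' `herv_logmean_high - herv_logmean_low` in log2 CPM. A per-sample latent
#' factor shared by all expressed hERV loci induces pairwise co-expression of
#' approximately `co_expression_rho` across samples; background genes are
#' independent. Counts are negative-binomial around log-normal means, and a
#' library size per sample is defined as the simulated column sum plus a
#' large inflation constant so that hERV CPMs remain a small fraction of the
#' library, as in real whole-transcriptome data.
#'
#' @param cfg A [sim_config()].
#' @return A list with `counts` (integer matrix, transcripts x samples),
#'   `library_sizes` (named integer vector), `herv_panel` (character, all
#'   hERV reference IDs), `is_tumor` (logical, all `TRUE`) and `truth`
#'   (cluster labels, silent-locus flags, per-sample latent factor).
#' @export
simulate_expression <- function(cfg) {
  validate_sim_config(cfg)
  if (cfg$n_herv < 2L) stop_("invalid config: n_herv must be >= 2")
  if (cfg$n_samples < 4L) stop_("invalid config: n_samples must be >= 4")

  set.seed(child_seed(cfg$seed, "expression"))
  ns <- cfg$n_samples
  sample_ids <- sprintf("S%03d", seq_len(ns))
  herv_ids <- sprintf("hERV_%04d", seq_len(cfg$n_herv))
  gene_ids <- sprintf("GENE_%05d", seq_len(cfg$n_background_genes))

  n_high <- round(cfg$cluster_fraction_high * ns)
  cluster <- sample(rep(c("high", "low"), c(n_high, ns - n_high)))
  names(cluster) <- sample_ids

  silent <- c(rep(TRUE, cfg$n_silent_herv),
              rep(FALSE, cfg$n_herv - cfg$n_silent_herv))
  silent <- silent[sample.int(cfg$n_herv)]
  names(silent) <- herv_ids

  # log2-CPM design: cluster mean + locus offset + shared factor + noise
  rho <- cfg$co_expression_rho
  u <- stats::rnorm(ns)                      # per-sample latent factor
  locus_offset <- stats::rnorm(cfg$n_herv, 0, 0.25)
  mu_cluster <- ifelse(cluster == "high",
                       cfg$herv_logmean_high, cfg$herv_logmean_low)
  eps <- matrix(stats::rnorm(cfg$n_herv * ns), cfg$n_herv, ns)
  log2cpm <- outer(locus_offset, mu_cluster, "+") +
    cfg$herv_logsd * (sqrt(rho) * matrix(u, cfg$n_herv, ns, byrow = TRUE) +
                      sqrt(1 - rho) * eps)
  log2cpm[silent, ] <- log2(0.01)            # ~0.01 CPM: below any floor

  bg_log2cpm <- matrix(stats::rnorm(cfg$n_background_genes * ns,
                                    mean = stats::rnorm(cfg$n_background_genes, 4, 1.5),
                                    sd = 0.3),
                       cfg$n_background_genes, ns)

  mu_counts <- 2^rbind(log2cpm, bg_log2cpm) * cfg$nominal_library / 1e6
  size <- 1 / cfg$dispersion
  counts <- matrix(stats::rnbinom(length(mu_counts), mu = mu_counts,
                                  size = size),
                   nrow(mu_counts), ns,
                   dimnames = list(c(herv_ids, gene_ids), sample_ids))
  storage.mode(counts) <- "integer"

  library_sizes <- as.integer(colSums(counts) + cfg$library_inflation)
  names(library_sizes) <- sample_ids

  list(counts = counts,
       library_sizes = library_sizes,
       herv_panel = herv_ids,
       is_tumor = stats::setNames(rep(TRUE, ns), sample_ids),
       truth = list(cluster = cluster, silent = silent, latent_factor = u))
}
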