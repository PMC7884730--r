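#' Counts-per-million normalization
#'
#' CPM for transcript t in sample s is `1e6 * count[t, s] / library_size[s]`.
#' Library sizes are totals of the sequenced library, not column sums of the
#' transcript subset, so hERV CPMs do not sum to one million.
#'
#' @param counts Non-negative integer matrix, transcripts x samples.
#' @param library_sizes Positive numeric vector, one entry per sample
#'   (matched by name when named, by position otherwise).
#' @return Numeric CPM matrix with the same dimnames as `counts`.
#' @export
compute_cpm <- function(counts, library_sizes) {
  if (ncol(counts) != length(library_sizes))
    stop_("counts has %d samples but %d library sizes given",
          ncol(counts), length(library_sizes))
  if (!is.null(names(library_sizes)) && !is.null(colnames(counts))) {
    if (!all(colnames(counts) %in% names(library_sizes)))
      stop_("library_sizes is missing samples present in counts")
    library_sizes <- library_sizes[colnames(counts)]
  }
  bad <- which(library_sizes <= 0)
  if (length(bad)) {
    nm <- if (!is.null(names(library_sizes))) names(library_sizes)[bad[1]]
          else as.character(bad[1])
    stop_("non-positive library size for sample '%s'", nm)
  }
  sweep(counts, 2, library_sizes, "/") * 1e6
}

#' Zero out sub-threshold CPM values
#'
#' Values strictly below `floor` are treated as sequencing noise and set to
#' zero; values at or above the floor pass through unchanged.
#'
#' @param cpm Numeric CPM matrix.
#' @param floor Noise threshold in CPM units (default 0.5).
#' @return Matrix with the floor applied.
#' @export
apply_noise_floor <- function(cpm, floor = 0.5) {
  if (floor < 0) stop_("noise floor must be >= 0")
  cpm[cpm < floor] <- 0
  cpm
}

#' Filter a reference panel to expressed transcripts
#'
#' A reference transcript is kept when its median CPM across tumor samples is
#' at least `median_floor`; transcripts with median CPM strictly below the
#' floor are considered not expressed and removed.
#'
#' @param cpm CPM matrix (after the noise floor, in the standard order of the
#'   pipeline).
#' @param reference_panel Character vector of candidate transcript IDs.
#' @param is_tumor Logical per sample; medians are taken over tumor samples
#'   only. Defaults to all samples being tumors.
#' @param median_floor Median-CPM threshold (default 0.1).
#' @return Character vector of retained transcript IDs with attributes
#'   `n_reference` and `n_retained`.
#' @export
filter_expressed <- function(cpm, reference_panel,
                             is_tumor = rep(TRUE, ncol(cpm)),
                             median_floor = 0.1) {
  if (!any(is_tumor)) stop_("no tumor samples to compute filtering medians")
  present <- intersect(reference_panel, rownames(cpm))
  med <- apply(cpm[present, is_tumor, drop = FALSE], 1, stats::median)
  retained <- present[med >= median_floor]
  structure(retained,
            n_reference = length(reference_panel),
            n_retained = length(retained))
}

#' Per-sample median hERV expression (median.hERV)
#'
#' The median of the (post-floor) CPM values of the retained hERV panel for
#' each sample. An even panel uses the midpoint-average median.
#'
#' @param cpm CPM matrix.
#' @param panel Non-empty character vector of retained hERV transcript IDs.
#' @return data.frame with `sample_id` and `median_herv`.
#' @export
median_herv <- function(cpm, panel) {
  if (length(panel) == 0) stop_("hERV panel is empty")
  missing <- setdiff(panel, rownames(cpm))
  if (length(missing))
    stop_("panel transcripts missing from matrix: %s",
          paste(utils::head(missing, 3), collapse = ", "))
  med <- apply(cpm[panel, , drop = FALSE], 2, stats::median)
  data.frame(sample_id = colnames(cpm), median_herv = unname(med),
             stringsAsFactors = FALSE)
}

#' Downsampling robustness of median.hERV
#'
#' Each round draws `ceiling(fraction * |panel|)` transcripts without
#' replacement, recomputes median.hERV, and records its Spearman rank
#' correlation across samples with the full-panel score.
#'
#' @param cpm CPM matrix.
#' @param panel Retained hERV panel (>= 2 transcripts).
#' @param fraction Fraction of the panel drawn per round, in (0, 1].
#' @param rounds Number of rounds (default 100).
#' @param seed Integer seed.
#' @return List with `scores` (rounds x samples matrix of per-round
#'   median.hERV), `spearman` (length-`rounds` vector) and `full` (the
#'   full-panel scores).
#' @export
downsampling_robustness <- function(cpm, panel, fraction = 0.8,
                                    rounds = 100L, seed = 1L) {
  if (length(panel) < 2) stop_("panel must contain at least 2 transcripts")
  if (fraction <= 0 || fraction > 1) stop_("fraction must be in (0, 1]")
  if (rounds < 1) stop_("rounds must be >= 1")
  full <- median_herv(cpm, panel)$median_herv
  k <- ceiling(fraction * length(panel))
  set.seed(child_seed(seed, "downsample"))
  scores <- matrix(NA_real_, rounds, ncol(cpm),
                   dimnames = list(NULL, colnames(cpm)))
  rho <- numeric(rounds)
  for (r in seq_len(rounds)) {
    sub <- sample(panel, k)
    scores[r, ] <- median_herv(cpm, sub)$median_herv
    rho[r] <- stats::cor(scores[r, ], full, method = "spearman")
  }
  list(scores = scores, spearman = rho, full = full)
}

#' Two-cluster hierarchical grouping of samples by hERV expression
#'
#' Samples are clustered by Ward linkage (`ward.D2`) on Euclidean distances
#' over per-transcript z-scored `log2(CPM + 1)` hERV profiles and the tree is
#' cut at k = 2. The cluster with the larger median of per-sample median.hERV
#' is labeled `"high"`.
#'
#' @param cpm CPM matrix (>= 4 samples).
#' @param panel Retained hERV panel.
#' @return Named character vector of `"high"` / `"low"` per sample.
#' @export
cluster_two <- function(cpm, panel) {
  if (ncol(cpm) < 4) stop_("need at least 4 samples to cluster")
  x <- log2(cpm[panel, , drop = FALSE] + 1)
  sds <- apply(x, 1, stats::sd)
  if (all(sds == 0))
    stop_("all hERV profiles are identical; no two-cluster structure")
  x <- x[sds > 0, , drop = FALSE]
  z <- t(scale(t(x)))   # z-score per transcript across samples
  hc <- stats::hclust(stats::dist(t(z)), method = "ward.D2")
  grp <- stats::cutree(hc, k = 2)
  mh <- median_herv(cpm, panel)$median_herv
  med1 <- stats::median(mh[grp == 1])
  med2 <- stats::median(mh[grp == 2])
  labels <- if (med1 >= med2) c("high", "low") else c("low", "high")
  stats::setNames(labels[grp], colnames(cpm))
}

#' Dichotomize a vector at its top fraction
#'
#' Labels `TRUE` every value at or above the `1 - fraction` empirical
#' quantile (linear-interpolation, type 7). Ties at the threshold are all
#' labeled `TRUE`, making the rule independent of input order.
#'
#' @param values Numeric vector (>= 2 finite values).
#' @param fraction Top fraction in (0, 1); default 0.30.
#' @return Logical vector (names preserved).
#' @export
dichotomize_top_fraction <- function(values, fraction = 0.30) {
  if (fraction <= 0 || fraction >= 1) stop_("fraction must be in (0, 1)")
  finite <- values[is.finite(values)]
  if (length(finite) < 2) stop_("need at least 2 finite values")
  if (max(finite) == min(finite)) {
    warning("all values identical; labeling every sample TRUE")
    return(stats::setNames(rep(TRUE, length(values)), names(values)))
  }
  thr <- stats::quantile(finite, 1 - fraction, type = 7, names = FALSE)
  values >= thr
}

#' Full hERV quantification stage
#'
#' Applies the fixed pipeline order: CPM, noise floor, expression filter,
#' median.hERV, two-cluster labels and the top-fraction dichotomization.
#'
#' @param counts Integer count matrix, transcripts x samples.
#' @param library_sizes Library size per sample.
#' @param reference_panel Candidate hERV transcript IDs.
#' @param is_tumor Logical per sample.
#' @param floor Noise floor in CPM (default 0.5).
#' @param median_floor Expression-filter median CPM (default 0.1).
#' @param top_fraction Dichotomization fraction (default 0.30).
#' @return List with `scores` (data.frame: sample_id, median_herv,
#'   herv_label, cluster_label), `panel` (retained IDs) and `cpm` (the
#'   floored CPM matrix).
#' @export
herv_quantify <- function(counts, library_sizes, reference_panel,
                          is_tumor = rep(TRUE, ncol(counts)),
                          floor = 0.5, median_floor = 0.1,
                          top_fraction = 0.30) {
  cpm <- compute_cpm(counts, library_sizes)
  cpm <- apply_noise_floor(cpm, floor)
  panel <- filter_expressed(cpm, reference_panel, is_tumor, median_floor)
  scores <- median_herv(cpm, panel)
  cluster <- cluster_two(cpm, panel)
  herv_high <- dichotomize_top_fraction(scores$median_herv, top_fraction)
  scores$herv_label <- ifelse(herv_high, "high", "low")
  scores$cluster_label <- unname(cluster[scores$sample_id])
  list(scores = scores, panel = panel, cpm = cpm)
}
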