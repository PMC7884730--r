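#' Filter a microsatellite site catalog
#'
#' Keeps noncoding mononucleotide homopolymers with reference repeat length
#' between `min_len` and `max_len` bases (inclusive) and removes any site on
#' the exclusion list (standing in for ethnicity-biased or chronically
#' low-coverage sites).
#'
#' @param sites data.frame with columns site_id, repeat_unit,
#'   ref_repeat_length and noncoding.
#' @param exclude Character vector of site IDs to drop.
#' @param min_len,max_len Inclusive repeat-length bounds (default 10-50).
#' @return The filtered data.frame.
#' @export
filter_site_catalog <- function(sites, exclude = character(),
                                min_len = 10L, max_len = 50L) {
  keep <- sites$noncoding &
    nchar(sites$repeat_unit) == 1L &
    sites$ref_repeat_length >= min_len &
    sites$ref_repeat_length <= max_len &
    !(sites$site_id %in% exclude)
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

hist_stats <- function(lengths, counts) {
  n <- sum(counts)
  if (n == 0) return(list(n = 0, mean = NA_real_, sd = NA_real_))
  m <- sum(lengths * counts) / n
  v <- sum(counts * (lengths - m)^2) / n
  list(n = n, mean = m, sd = sqrt(v))
}

#' Assess one microsatellite site for instability
#'
#' Compares the read-weighted mean repeat length of the tumor histogram with
#' the reference "known range": reference mean plus/minus `k_sd` reference
#' standard deviations. In paired mode the reference is the matched normal's
#' histogram; in baseline mode it is the set of per-sample mean lengths of a
#' baseline panel. Sites with fewer than `min_reads` tumor or reference
#' reads are not assessed.
#'
#' @param tumor data.frame with columns `length` and `count` (the tumor
#'   histogram for one site).
#' @param reference Either one histogram data.frame (paired mode) or a list
#'   of histogram data.frames, one per baseline sample (baseline mode).
#' @param min_reads Minimum reads to assess (default 20).
#' @param k_sd Width of the known range in reference SDs (default 3).
#' @return One of `"stable"`, `"unstable"`, `"not_assessed"`.
#' @export
assess_site <- function(tumor, reference, min_reads = 20L, k_sd = 3) {
  ts <- if (is.null(tumor) || nrow(tumor) == 0) list(n = 0)
        else hist_stats(tumor$length, tumor$count)
  if (ts$n < min_reads) return("not_assessed")

  if (is.data.frame(reference)) {
    rs <- if (nrow(reference) == 0) list(n = 0)
          else hist_stats(reference$length, reference$count)
    if (rs$n < min_reads) return("not_assessed")
    centre <- rs$mean
    spread <- rs$sd
  } else {
    means <- ns <- numeric(0)
    for (h in reference) {
      s <- if (is.null(h) || nrow(h) == 0) list(n = 0)
           else hist_stats(h$length, h$count)
      if (s$n >= min_reads) {
        means <- c(means, s$mean)
        ns <- c(ns, s$n)
      }
    }
    if (length(means) == 0) return("not_assessed")
    centre <- mean(means)
    spread <- if (length(means) > 1) stats::sd(means) else {
      # a single-sample baseline degenerates to paired mode
      h <- reference[[1]]
      hist_stats(h$length, h$count)$sd
    }
  }
  if (ts$mean < centre - k_sd * spread || ts$mean > centre + k_sd * spread)
    "unstable" else "stable"
}

#' Roll site verdicts up into an MSI score and classification
#'
#' The MSI score is the number of unstable sites divided by the number of
#' assessed sites. A tumor is MSI-H when the score is at or above the
#' pipeline threshold: 0.30 for the paired whole-exome pipeline and 0.20 for
#' the baseline targeted-panel pipeline.
#'
#' @param verdicts Character vector of per-site verdicts from
#'   [assess_site()].
#' @param pipeline_mode `"paired_wes"` or `"baseline_panel"`.
#' @param threshold Override of the mode's default threshold.
#' @return List: n_assessed, n_unstable, msi_score, classification,
#'   pipeline_mode.
#' @export
msi_score_and_classify <- function(verdicts,
                                   pipeline_mode = c("paired_wes",
                                                     "baseline_panel"),
                                   threshold = NULL) {
  pipeline_mode <- match.arg(pipeline_mode)
  assessed <- verdicts[verdicts != "not_assessed"]
  if (length(assessed) == 0)
    stop_("no assessed sites; MSI score is undefined")
  if (is.null(threshold))
    threshold <- if (pipeline_mode == "paired_wes") 0.30 else 0.20
  n_unstable <- sum(assessed == "unstable")
  score <- n_unstable / length(assessed)
  list(n_assessed = length(assessed), n_unstable = n_unstable,
       msi_score = score,
       classification = if (score >= threshold) "MSI-H" else "MSS",
       pipeline_mode = pipeline_mode)
}

#' Score MSI for every tumor sample from a histogram table
#'
#' @param sites Filtered site catalog ([filter_site_catalog()]).
#' @param histograms Long data.frame (site_id, sample_id, tissue, length,
#'   count) with `tissue` in tumor/normal. In paired mode each tumor site is
#'   assessed against the same sample's normal; in baseline mode against the
#'   normals of `baseline_ids` (default: all samples).
#' @param pipeline_mode `"paired_wes"` or `"baseline_panel"`.
#' @param baseline_ids Baseline sample IDs (baseline mode only).
#' @param min_reads,k_sd See [assess_site()].
#' @param threshold Optional threshold override.
#' @return data.frame: sample_id, n_assessed, n_unstable, msi_score,
#'   classification, pipeline_mode; per-site verdicts in attribute
#'   `"verdicts"` (sites x samples).
#' @export
call_msi <- function(sites, histograms,
                     pipeline_mode = c("paired_wes", "baseline_panel"),
                     baseline_ids = NULL, min_reads = 20L, k_sd = 3,
                     threshold = NULL) {
  pipeline_mode <- match.arg(pipeline_mode)
  sample_ids <- sort(unique(histograms$sample_id))
  if (is.null(baseline_ids)) baseline_ids <- sample_ids
  split_hist <- split(histograms,
                      list(histograms$site_id, histograms$sample_id,
                           histograms$tissue), drop = TRUE)
  get_h <- function(site, sample, tissue) {
    split_hist[[paste(site, sample, tissue, sep = ".")]]
  }
  verdicts <- matrix(NA_character_, nrow(sites), length(sample_ids),
                     dimnames = list(sites$site_id, sample_ids))
  for (site in sites$site_id) {
    baseline <- if (pipeline_mode == "baseline_panel")
      lapply(baseline_ids, function(s) get_h(site, s, "normal"))
    for (s in sample_ids) {
      tum <- get_h(site, s, "tumor")
      ref <- if (pipeline_mode == "paired_wes") {
        h <- get_h(site, s, "normal")
        if (is.null(h)) h <- data.frame(length = integer(), count = integer())
        h
      } else baseline
      if (is.null(tum)) tum <- data.frame(length = integer(),
                                          count = integer())
      verdicts[site, s] <- assess_site(tum, ref, min_reads, k_sd)
    }
  }
  res <- do.call(rbind, lapply(sample_ids, function(s) {
    sc <- msi_score_and_classify(verdicts[, s], pipeline_mode, threshold)
    data.frame(sample_id = s, n_assessed = sc$n_assessed,
               n_unstable = sc$n_unstable, msi_score = sc$msi_score,
               classification = sc$classification,
               pipeline_mode = sc$pipeline_mode,
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  attr(res, "verdicts") <- verdicts
  res
}

#' Classify the 5-marker MSI-PCR panel
#'
#' The Promega-style mononucleotide panel (BAT-25, BAT-26, NR-21, NR-24,
#' MONO-27) calls a tumor MSI-High when two or more markers are altered.
#' Pentanucleotide identity markers (Penta C / Penta D) are accepted but
#' only trigger a sample-mismatch warning when discordant.
#'
#' @param marker_altered Logical vector of length 5, named by marker.
#' @param penta_concordant Optional logical; `FALSE` warns about a possible
#'   tumor/normal sample mismatch.
#' @return `"MSI-H"` or `"not MSI-H"`.
#' @export
msi_pcr_classify <- function(marker_altered, penta_concordant = NULL) {
  if (length(marker_altered) != 5L)
    stop_("expected exactly 5 mononucleotide marker calls, got %d",
          length(marker_altered))
  if (!is.logical(marker_altered) || anyNA(marker_altered))
    stop_("marker calls must be non-missing logicals")
  if (!is.null(penta_concordant) && !isTRUE(penta_concordant))
    warning("pentanucleotide identity markers discordant; ",
            "possible tumor/normal sample mismatch")
  if (sum(marker_altered) >= 2L) "MSI-H" else "not MSI-H"
}

#' Default mononucleotide MSI-PCR marker names
#' @export
msi_pcr_markers <- function() c("BAT-25", "BAT-26", "NR-21", "NR-24",
                                "MONO-27")
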