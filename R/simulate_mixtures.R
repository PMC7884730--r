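#' Simulate purified immune-cell and background expression profiles
#'
#' Builds CPM-scale expression profiles for a set of immune cell types
#' (CD4, CD8, CD19 by default) and one or more background tissues. Each cell
#' type carries `markers_per_type` planted marker genes that are highly
#' expressed in that type only; all remaining genes follow a shared baseline
#' so that no housekeeping gene can masquerade as a marker. Profiles are
#' normalized to sum to one million (CPM).
#'
#' @param n_genes Total number of genes.
#' @param cell_types Character vector of cell-type names.
#' @param backgrounds Character vector of background tissue names.
#' @param markers_per_type Number of marker genes planted per cell type.
#' @param marker_cpm Geometric-mean CPM of a marker in its own cell type.
#' @param offtarget_cpm CPM of a marker gene everywhere else.
#' @param seed Integer seed.
#' @return List with `purified` (genes x cell types), `background`
#'   (genes x backgrounds) and `truth_markers` (list of planted marker IDs
#'   per cell type).
#' @export
simulate_immune_profiles <- function(n_genes = 1000L,
                                     cell_types = c("CD4", "CD8", "CD19"),
                                     backgrounds = "colon",
                                     markers_per_type = 30L,
                                     marker_cpm = 300,
                                     offtarget_cpm = 2,
                                     seed = 1L) {
  set.seed(child_seed(seed, "profiles"))
  nt <- length(cell_types)
  if (n_genes < nt * markers_per_type + 10L)
    stop_("n_genes too small for %d markers per each of %d cell types",
          markers_per_type, nt)
  gene_ids <- sprintf("IMM_%05d", seq_len(n_genes))
  baseline <- stats::rexp(n_genes, rate = 1 / 50)
  purified <- vapply(cell_types, function(ct)
    baseline * exp(stats::rnorm(n_genes, 0, 0.1)), numeric(n_genes))
  background <- vapply(backgrounds, function(b)
    baseline * exp(stats::rnorm(n_genes, 0, 0.1)), numeric(n_genes))
  dimnames(purified) <- list(gene_ids, cell_types)
  dimnames(background) <- list(gene_ids, backgrounds)

  truth_markers <- list()
  for (i in seq_len(nt)) {
    idx <- ((i - 1L) * markers_per_type + 1L):(i * markers_per_type)
    purified[idx, ] <- offtarget_cpm
    purified[idx, i] <- exp(stats::rnorm(markers_per_type,
                                         log(marker_cpm), 0.5))
    background[idx, ] <- offtarget_cpm
    truth_markers[[cell_types[i]]] <- gene_ids[idx]
  }
  purified <- apply(purified, 2, function(v) v / sum(v) * 1e6)
  background <- apply(background, 2, function(v) v / sum(v) * 1e6)
  list(purified = purified, background = background,
       truth_markers = truth_markers)
}

#' Simulate bulk mixtures of immune cells in a tissue background
#'
#' Forms in-silico titrations: each mixture is the convex combination
#' `sum_c f_c * S[, c] + (1 - sum_c f_c) * B`, multiplied by i.i.d.
#' log-normal noise with log-scale standard deviation `noise_sd`. This is
#' the generative model under which absolute-fraction deconvolution is
#' exactly linear, mirroring wet-lab titrations of purified CD4+/CD8+/CD19+
#' RNA into normal-tissue RNA.
#'
#' @param purified Genes x cell-types matrix of purified profiles (CPM).
#' @param background Numeric vector (or 1-column matrix) of the background
#'   tissue profile on the same gene index.
#' @param fractions Mixtures x cell-types matrix of true fractions; each row
#'   must sum to at most 1.
#' @param noise_sd Log-scale standard deviation of multiplicative noise.
#' @param seed Integer seed.
#' @return List with `mixtures` (genes x mixtures matrix) and `truth`
#'   (data.frame of mixture_id and the true fraction per cell type).
#' @export
simulate_mixtures <- function(purified, background, fractions,
                              noise_sd = 0.1, seed = 1L) {
  if (is.matrix(background)) background <- background[, 1]
  if (!identical(rownames(purified), names(background)) &&
      !is.null(names(background)))
    stop_("purified and background profiles must share a gene index")
  fractions <- as.matrix(fractions)
  if (ncol(fractions) != ncol(purified))
    stop_("fractions must have one column per cell type")
  rs <- rowSums(fractions)
  if (any(rs > 1 + 1e-12))
    stop_("fraction row sums must be <= 1 (row %d sums to %.3f)",
          which.max(rs), max(rs))
  set.seed(child_seed(seed, "mixtures"))
  n_mix <- nrow(fractions)
  clean <- purified %*% t(fractions) +
    outer(background, 1 - rs)
  noise <- matrix(exp(stats::rnorm(length(clean), 0, noise_sd)),
                  nrow(clean), n_mix)
  mixtures <- clean * noise
  mix_ids <- sprintf("MIX_%03d", seq_len(n_mix))
  colnames(mixtures) <- mix_ids
  rownames(mixtures) <- rownames(purified)
  truth <- data.frame(mixture_id = mix_ids, fractions,
                      row.names = NULL, check.names = FALSE)
  list(mixtures = mixtures, truth = truth)
}
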