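#' Select cell-type signature genes against explicit backgrounds
#'
#' A gene is a signature gene for a cell type when (i) its expression in that
#' type is at least `expr_min`, and (ii) it exceeds `fold_min`-fold both the
#' maximum across all background tissues and the maximum across every other
#' cell type. The top `max_genes_per_type` genes by that fold change are
#' kept per type.
#'
#' @param purified Genes x cell-types matrix of purified profiles (CPM).
#' @param background Genes x tissues matrix (or vector) of background
#'   profiles on the same gene index.
#' @param fold_min Minimum fold change over background and other types.
#' @param expr_min Minimum expression in the target type (CPM).
#' @param max_genes_per_type Cap on genes per cell type.
#' @return Named list of character vectors of gene IDs per cell type.
#' @export
select_signature_genes <- function(purified, background, fold_min = 5,
                                   expr_min = 20,
                                   max_genes_per_type = 100L) {
  if (!is.matrix(background)) background <- cbind(bg = background)
  if (nrow(background) != nrow(purified))
    stop_("purified and background profiles must share a gene index")
  types <- colnames(purified)
  bg_max <- apply(background, 1, max)
  out <- list()
  for (ct in types) {
    other_max <- apply(purified[, setdiff(types, ct), drop = FALSE], 1, max)
    ref <- pmax(bg_max, other_max)
    fold <- purified[, ct] / pmax(ref, .Machine$double.eps)
    ok <- purified[, ct] >= expr_min & fold >= fold_min
    if (!any(ok))
      stop_("no signature gene passes for cell type '%s'", ct)
    sel <- rownames(purified)[ok][order(fold[ok], decreasing = TRUE)]
    out[[ct]] <- utils::head(sel, max_genes_per_type)
  }
  out
}

#' Place cell-type signatures on a common scale
#'
#' Each cell type's signature column is rescaled so that its mean over its
#' own selected genes equals `scale_constant`. The applied per-type scale
#' factors are stored so that regression coefficients can be mapped back to
#' absolute fractions in the original expression units.
#'
#' @param purified Genes x cell-types purified profile matrix.
#' @param gene_sets Output of [select_signature_genes()].
#' @param scale_constant Common target mean (default 100).
#' @return An `immune_signatures` object: `matrix` (signature genes x cell
#'   types, normalized), `gene_sets`, `scale_factors` (per type) and
#'   `scale_constant`.
#' @export
normalize_signatures <- function(purified, gene_sets, scale_constant = 100) {
  types <- names(gene_sets)
  genes <- unique(unlist(gene_sets))
  raw <- purified[genes, types, drop = FALSE]
  scale_factors <- vapply(types, function(ct) {
    m <- mean(purified[gene_sets[[ct]], ct])
    if (m <= 0) stop_("all-zero signature for cell type '%s'", ct)
    scale_constant / m
  }, numeric(1))
  mat <- sweep(raw, 2, scale_factors, "*")
  structure(list(matrix = mat, gene_sets = gene_sets,
                 scale_factors = scale_factors,
                 scale_constant = scale_constant),
            class = "immune_signatures")
}

#' @export
print.immune_signatures <- function(x, ...) {
  cat("immune_signatures:", ncol(x$matrix), "cell types,",
      nrow(x$matrix), "genes, common scale", x$scale_constant, "\n")
  invisible(x)
}

#' Build an immune signature set in one step
#'
#' @inheritParams select_signature_genes
#' @inheritParams normalize_signatures
#' @return An `immune_signatures` object.
#' @export
build_signatures <- function(purified, background, fold_min = 5,
                             expr_min = 20, max_genes_per_type = 100L,
                             scale_constant = 100) {
  gene_sets <- select_signature_genes(purified, background, fold_min,
                                      expr_min, max_genes_per_type)
  normalize_signatures(purified, gene_sets, scale_constant)
}

#' Absolute-fraction deconvolution of one bulk mixture
#'
#' Fits nu-support-vector regression (linear kernel) of the mixture on the
#' normalized signature columns over the signature genes, trying
#' `nu in {0.25, 0.5, 0.75}` and keeping the solution with the lowest RMSE.
#' Negative coefficients are clamped to zero and coefficients are mapped
#' back through the per-type scale factors to absolute RNA fractions; no
#' sum-to-one renormalization is applied, which is what distinguishes
#' absolute from relative deconvolution. The full mixture profile is first
#' re-anchored to CPM (sum 1e6) so the result is invariant to overall
#' library scaling.
#'
#' @param mixture Named numeric vector: the bulk expression profile on (a
#'   superset of) the signature gene index, CPM-like scale.
#' @param signatures An `immune_signatures` object.
#' @param nu_grid nu values tried (default `c(0.25, 0.5, 0.75)`).
#' @param renormalize Re-anchor `mixture` to sum 1e6 before fitting
#'   (default `TRUE`).
#' @return List with `fractions` (named, >= 0), `residual_rmse` and
#'   `converged`.
#' @export
deconvolve <- function(mixture, signatures,
                       nu_grid = c(0.25, 0.5, 0.75), renormalize = TRUE) {
  S <- signatures$matrix
  genes <- rownames(S)
  n_missing <- sum(!genes %in% names(mixture))
  if (n_missing > 0.2 * length(genes))
    stop_("mixture is missing %d of %d signature genes (> 20%%)",
          n_missing, length(genes))
  if (renormalize) mixture <- mixture / sum(mixture, na.rm = TRUE) * 1e6
  y <- mixture[genes]
  keep <- !is.na(y)
  y <- y[keep]
  X <- S[keep, , drop = FALSE]

  # joint working rescale keeps coefficients unchanged while placing the
  # problem in a range where the solver converges quickly
  k <- signatures$scale_constant / 10
  Xw <- X / k
  yw <- y / k

  best <- NULL
  best_rmse <- Inf
  converged <- TRUE
  for (nu in nu_grid) {
    w <- tryCatch(
      withCallingHandlers({
        fit <- e1071::svm(x = Xw, y = yw, type = "nu-regression",
                          kernel = "linear", nu = nu, cost = 10,
                          scale = FALSE, tolerance = 1e-6)
        drop(t(fit$coefs) %*% fit$SV)
      }, warning = function(w) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }),
      # an empty model (no support vectors) means the flat fit w = 0 already
      # sits inside the epsilon tube, e.g. a mixture with no immune content
      error = function(e) rep(0, ncol(Xw)))
    w <- pmax(w, 0)
    rmse <- sqrt(mean((drop(Xw %*% w) - yw)^2))
    if (rmse < best_rmse) {
      best <- w
      best_rmse <- rmse
    }
  }
  # coefficient c_t satisfies mixture ~= sum_t c_t * (alpha_t * S_raw[, t]),
  # so the absolute fraction is c_t * alpha_t with alpha_t the stored factor
  fractions <- best * signatures$scale_factors
  names(fractions) <- colnames(S)
  list(fractions = fractions, residual_rmse = best_rmse * k,
       converged = converged)
}

#' Deconvolve every column of a mixture matrix
#'
#' @param mixtures Genes x samples matrix.
#' @param signatures An `immune_signatures` object.
#' @param ... Passed to [deconvolve()].
#' @return data.frame: sample_id, one column per cell type, residual_rmse,
#'   converged.
#' @export
deconvolve_matrix <- function(mixtures, signatures, ...) {
  res <- lapply(colnames(mixtures), function(s) {
    d <- deconvolve(mixtures[, s], signatures, ...)
    c(list(sample_id = s), as.list(d$fractions),
      list(residual_rmse = d$residual_rmse, converged = d$converged))
  })
  out <- do.call(rbind, lapply(res, as.data.frame,
                               stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Titration linearity validation of the deconvolution
#'
#' Simulates in-silico titrations of each cell type into the background via
#' [simulate_mixtures()], deconvolves every mixture, and reports the squared
#' Pearson correlation (R^2) between predicted and true fractions per cell
#' type, plus the median across types.
#'
#' @param signatures An `immune_signatures` object.
#' @param purified Genes x cell-types purified profile matrix used to form
#'   the mixtures.
#' @param background Background tissue profile vector.
#' @param fraction_grid True fractions titrated (>= 3 distinct values).
#' @param reps Replicates per grid point.
#' @param noise_sd Log-normal noise sd of the simulated mixtures.
#' @param seed Integer seed.
#' @return List with `r2` (named per cell type), `median_r2` and `results`
#'   (long data.frame of true and predicted fractions).
#' @export
titration_validation <- function(signatures, purified, background,
                                 fraction_grid = c(0, 0.05, 0.1, 0.2, 0.4),
                                 reps = 3L, noise_sd = 0.1, seed = 1L) {
  if (length(unique(fraction_grid)) < 3)
    stop_("fraction_grid must contain at least 3 distinct fractions")
  types <- colnames(signatures$matrix)
  rows <- list()
  for (ct in types) {
    fr <- matrix(0, length(fraction_grid) * reps, length(types),
                 dimnames = list(NULL, types))
    fr[, ct] <- rep(fraction_grid, each = reps)
    sim <- simulate_mixtures(purified, background, fr, noise_sd,
                             seed = child_seed(seed, ct))
    dec <- deconvolve_matrix(sim$mixtures, signatures)
    rows[[ct]] <- data.frame(cell_type = ct,
                             true_fraction = fr[, ct],
                             predicted_fraction = dec[[ct]],
                             stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)
  r2 <- vapply(types, function(ct) {
    d <- results[results$cell_type == ct, ]
    stats::cor(d$true_fraction, d$predicted_fraction)^2
  }, numeric(1))
  list(r2 = r2, median_r2 = stats::median(r2), results = results)
}
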