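# Shared fixtures, built once per test run.

small_cfg <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_samples = 20L, n_herv = 60L,
               n_silent_herv = 10L, n_background_genes = 200L,
               msi_n_sites = 40L)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# immune profiles + signatures reused across deconvolution tests
fixture_profiles <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      prof <- simulate_immune_profiles(seed = 42L)
      sig <- build_signatures(prof$purified, prof$background)
      cache <<- list(profiles = prof, signatures = sig)
    }
    cache
  }
})

# noise-free convex mixture of profiles, used by several oracles
make_mixture <- function(prof, fractions) {
  drop(prof$purified %*% fractions) +
    (1 - sum(fractions)) * prof$background[, 1]
}

# single somatic variant record with every filter field populated
make_variant <- function(vaf_t = 0.20, vaf_n = 0.01, dp_t = 100L,
                         dp_n = 40L, ad_t = 20L, both = TRUE,
                         gene = "", pathogenic = FALSE) {
  data.frame(sample_id = "S1", chrom = "chr1", pos = 1L, ref = "A",
             alt = "T", vaf_tumor = vaf_t, vaf_normal = vaf_n,
             dp_tumor = dp_t, dp_normal = dp_n, ad_tumor = ad_t,
             both_strands = both, gene = gene, pathogenic = pathogenic,
             stringsAsFactors = FALSE)
}

# worked filter fixture: one violation of each rule plus two clean records
eight_record_table <- function() {
  rbind(
    make_variant(),                                        # clean
    make_variant(vaf_t = 0.04, dp_t = 400L, ad_t = 16L),   # VAF rule
    make_variant(dp_t = 49L, ad_t = 10L, vaf_t = 10 / 49), # DP tumor
    make_variant(dp_n = 19L),                              # DP normal
    make_variant(dp_t = 60L, ad_t = 4L, vaf_t = 4 / 60),   # AD tumor
    make_variant(vaf_t = 0.25, ad_t = 25L, vaf_n = 0.05),  # ratio == 0.2
    make_variant(both = FALSE),                            # strands
    make_variant(vaf_t = 0.30, ad_t = 30L)                 # clean
  )
}

# independent adjusted Rand index (mclust) for cluster-recovery oracles
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# exhaustive simplex grid-search deconvolution oracle: least squares of the
# full generative model (signatures plus background remainder) over the
# signature genes, step 0.01
grid_search_fractions <- function(mixture, signatures, background,
                                  step = 0.01) {
  genes <- rownames(signatures$matrix)
  S <- signatures$matrix %*% diag(signatures$scale_factors^-1)  # raw units
  colnames(S) <- colnames(signatures$matrix)
  y <- mixture[genes]
  bg <- background[genes]
  grid <- seq(0, 1, by = step)
  best <- NULL
  best_rss <- Inf
  for (f1 in grid) {
    rest <- expand.grid(f2 = grid, f3 = grid)
    rest <- rest[f1 + rest$f2 + rest$f3 <= 1 + 1e-12, ]
    if (!nrow(rest)) next
    FF <- rbind(f1, t(as.matrix(rest)))
    resid <- (S %*% FF + outer(bg, 1 - colSums(FF))) - y
    rss <- colSums(resid^2)
    i <- which.min(rss)
    if (rss[i] < best_rss) {
      best_rss <- rss[i]
      best <- FF[, i]
    }
  }
  stats::setNames(as.numeric(best), colnames(S))
}
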