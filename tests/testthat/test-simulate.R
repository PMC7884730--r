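test_that("identical configurations reproduce identical bundles, on disk too", {
  cfg <- small_cfg(seed = 7L)
  b1 <- simulate_cohort_bundle(cfg)
  b2 <- simulate_cohort_bundle(cfg)
  expect_identical(b1$counts, b2$counts)
  expect_identical(b1$variants, b2$variants)
  expect_identical(b1$clinical, b2$clinical)
  expect_identical(b1$truth, b2$truth)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_bundle(b1, d1)
  write_bundle(b2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("bundle files round-trip through the pipeline readers", {
  b <- simulate_cohort_bundle(small_cfg(seed = 3L))
  d <- withr::local_tempdir()
  write_bundle(b, d)
  r <- read_bundle(d)
  expect_identical(unname(b$counts), unname(r$counts))
  expect_identical(unname(b$library_sizes), unname(r$library_sizes))
  expect_equal(b$purified_profiles, r$purified_profiles, tolerance = 1e-6)
  expect_equal(b$immune_mixtures, r$immune_mixtures, tolerance = 1e-6)
  expect_identical(b$clinical$id, r$clinical$id)
  expect_identical(b$truth$msi_status, r$truth$msi_status)
  expect_identical(b$truth$cluster, r$truth$cluster)

  # VCF records sorted by chromosome then position
  v <- r$variants
  cn <- as.integer(sub("chr", "", v$chrom))
  expect_true(all(diff(order(order(cn, v$pos))) == 1))
  expect_equal(nrow(v), nrow(b$variants))
  expect_equal(sort(v$pos), sort(b$variants$pos))
})

test_that("expression generator rejects degenerate configurations", {
  expect_error(sim_config(n_samples = 3L), "n_samples")
  expect_error(sim_config(n_herv = 1L), "n_herv")
  expect_error(sim_config(co_expression_rho = 1.2), "proportions")
  expect_error(sim_config(hazard_ratios = c(g = -1)), "hazard")
})

test_that("noise-free mixtures reproduce the linear model exactly", {
  prof <- fixture_profiles()$profiles
  fr <- rbind(c(0.2, 0.1, 0.05), c(0, 0, 0), c(0, 1, 0))
  sim <- simulate_mixtures(prof$purified, prof$background[, 1], fr,
                           noise_sd = 0, seed = 1L)
  expected <- sapply(1:3, function(i) make_mixture(prof, fr[i, ]))
  expect_lt(max(abs(sim$mixtures - expected)), 1e-9)
  # all-zero fractions give back the background; a pure fraction gives the
  # purified profile itself
  expect_lt(max(abs(sim$mixtures[, 2] - prof$background[, 1])), 1e-9)
  expect_lt(max(abs(sim$mixtures[, 3] - prof$purified[, "CD8"])), 1e-9)
})

test_that("mixture fractions above one are rejected", {
  prof <- fixture_profiles()$profiles
  expect_error(
    simulate_mixtures(prof$purified, prof$background[, 1],
                      rbind(c(0.6, 0.5, 0.1)), 0, 1L),
    "row sums")
})

test_that("cluster-recovery accuracy is monotone in the planted separation", {
  seps <- c(0, 1, 2)
  mean_ari <- sapply(seps, function(sep) {
    mean(sapply(1:3, function(seed) {
      cfg <- sim_config(seed = seed, n_samples = 40L, n_herv = 100L,
                        n_silent_herv = 0L, n_background_genes = 50L,
                        herv_logmean_low = 1, herv_logmean_high = 1 + sep)
      e <- simulate_expression(cfg)
      cpm <- apply_noise_floor(compute_cpm(e$counts, e$library_sizes))
      ari(cluster_two(cpm, e$herv_panel), e$truth$cluster)
    }))
  })
  expect_true(all(diff(mean_ari) >= -0.02))
  # no separation leaves recovery at chance
  expect_lt(mean_ari[1], 0.3)
})

test_that("MSI generator honors its instability rates", {
  cfg0 <- small_cfg(seed = 5L, msi_unstable_rate_msih = 0,
                    msi_unstable_rate_mss = 0)
  m0 <- simulate_msi_data(cfg0)
  expect_false(any(m0$truth$unstable_sites))

  # zero-coverage tumor site is emitted but cannot be assessed
  empty <- data.frame(length = integer(), count = integer())
  normal <- data.frame(length = c(14, 15, 16), count = c(20, 60, 20))
  expect_identical(assess_site(empty, normal), "not_assessed")
})

test_that("variant generator truth flags agree with the filter rules", {
  v <- simulate_variants(small_cfg(seed = 11L), violation_rate = 0.3)
  f <- filter_somatic(v$variants)
  expect_identical(nrow(f$retained), sum(v$truth$passes_filter))
  expect_identical(f$retained$pos,
                   v$variants$pos[v$truth$passes_filter])
  # an injected low-VAF record is removed
  inj <- v$variants[1, ]
  inj$dp_tumor <- 400L; inj$ad_tumor <- 16L; inj$vaf_tumor <- 0.04
  inj$pos <- -1L
  f2 <- filter_somatic(rbind(v$variants, inj))
  expect_false(-1L %in% f2$retained$pos)
})

test_that("an empty variant table yields zero TMB", {
  cfg <- small_cfg(seed = 2L, n_variants_mean = 0, msi_fraction_msih = 0)
  v <- simulate_variants(cfg, lynch_fraction = 0)
  expect_identical(nrow(v$variants), 0L)
  f <- filter_somatic(v$variants)
  expect_equal(compute_tmb(nrow(f$retained), 30), 0)
})

test_that("survival generator has calibrated null behavior and recovers HRs", {
  # under equal hazards the log-rank test keeps its nominal type-I error
  rej <- mean(sapply(1:500, function(s) {
    d <- simulate_survival(rep(c("A", "B"), each = 40),
                           hazard_ratios = c(A = 1, B = 1),
                           censoring_rate = 0.2, seed = s)
    km_logrank(d$os_months, d$os_event,
               rep(c("A", "B"), each = 40))$logrank_p < 0.05
  }))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)

  # Cox CI covers a true HR of 4.4 in most replicates at n = 500
  labels <- rep(c("base", "WTS-"), c(350, 150))
  cover <- mean(sapply(1:50, function(s) {
    d <- simulate_survival(labels, c("WTS-" = 4.4), censoring_rate = 0.3,
                           seed = s)
    fit <- cox_fit(d$os_months, d$os_event,
                   data.frame(flag = labels == "WTS-"), "univariate")
    fit$ci_lower <= 4.4 && 4.4 <= fit$ci_upper
  }))
  expect_gte(cover, 0.9)
})

test_that("full censoring is produced and survives KM gracefully", {
  d <- simulate_survival(rep("A", 20), c(A = 1), censoring_rate = 1,
                         seed = 1L)
  expect_true(all(d$os_event == 0))
  fit <- km_logrank(c(d$os_months, d$os_months),
                    c(d$os_event, d$os_event),
                    rep(c("A", "B"), each = 20))
  expect_true(all(is.na(fit$table$median_months)))
  expect_error(simulate_survival("A", c(A = 0)), "> 0")
})
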