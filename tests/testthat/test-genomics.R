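test_that("the crafted eight-record table is filtered rule by rule", {
  f <- filter_somatic(eight_record_table())
  expect_identical(nrow(f$retained), 2L)
  expect_identical(unname(f$rejections), rep(1L, 6))
  expect_equal(f$retained$vaf_tumor, c(0.20, 0.30))
})

test_that("filter boundaries are strict where the rules say so", {
  # VAF ratio exactly 0.2 is rejected; just below passes
  at <- make_variant(vaf_t = 0.25, ad_t = 25L, vaf_n = 0.25 * 0.2)
  below <- make_variant(vaf_t = 0.25, ad_t = 25L, vaf_n = 0.25 * 0.2 - 1e-9)
  expect_identical(nrow(filter_somatic(at)$retained), 0L)
  expect_identical(nrow(filter_somatic(below)$retained), 1L)
  # depth 49 fails, 50 passes; VAF 0.05 passes
  expect_identical(nrow(filter_somatic(
    make_variant(dp_t = 50L))$retained), 1L)
  expect_identical(nrow(filter_somatic(
    make_variant(vaf_t = 0.05, ad_t = 5L))$retained), 1L)
  # zero tumor VAF is caught by the VAF rule, not the ratio
  f0 <- filter_somatic(make_variant(vaf_t = 0, ad_t = 0L, vaf_n = 0))
  expect_identical(unname(f0$rejections["vaf_tumor"]), 1L)
})

test_that("the somatic filter is idempotent", {
  v <- simulate_variants(small_cfg(seed = 21L), violation_rate = 0.3)
  once <- filter_somatic(v$variants)$retained
  twice <- filter_somatic(once)$retained
  expect_identical(once, twice)
})

test_that("TMB is mutations per megabase", {
  expect_equal(compute_tmb(300, 30), 10)
  expect_equal(compute_tmb(0, 30), 0)
  f <- filter_somatic(eight_record_table())
  expect_equal(compute_tmb(nrow(f$retained), 1), 2)
  expect_error(compute_tmb(5, 0), "> 0")
})

test_that("arm events use a strict 20 percent threshold", {
  expect_true(arm_events(100, 21, 0)$deleted)
  expect_false(arm_events(100, 20, 0)$deleted)
  both <- arm_events(100, 21, 30)
  expect_true(both$deleted && both$amplified)
  expect_error(arm_events(0, 0, 0), "genes")
  expect_error(arm_events(10, 6, 6), "exceed")
})

test_that("arm events are invariant to gene order and to re-aggregation", {
  set.seed(31)
  calls <- sample(c("del", "neutral", "amp"), 60, TRUE, c(0.3, 0.6, 0.1))
  ev <- function(x) {
    e <- arm_events(length(x), sum(x == "del"), sum(x == "amp"))
    c(e$deleted, e$amplified)
  }
  expect_identical(ev(calls), ev(sample(calls)))
  # counts aggregated over split sub-lists give the same event call
  parts <- split(calls, rep(1:3, each = 20))
  agg <- arm_events(60, sum(sapply(parts, function(p) sum(p == "del"))),
                    sum(sapply(parts, function(p) sum(p == "amp"))))
  expect_identical(c(agg$deleted, agg$amplified), ev(calls))
})

test_that("CIN burden classifies by cohort tertiles, monotonically", {
  calls <- expand.grid(gene = sprintf("g%02d", 1:30),
                       sample_id = sprintf("s%02d", 1:9),
                       stringsAsFactors = FALSE)
  calls$arm <- rep(rep(c("1p", "1q", "2p"), each = 10), 9)
  calls$call <- "neutral"
  # plant 0 / 1 / 3 arm events for three groups of samples
  n_events <- rep(c(0, 1, 3), each = 3)
  for (i in seq_len(9)) {
    if (n_events[i] == 0) next
    arms <- c("1p", "1q", "2p")[seq_len(n_events[i] %% 4)]
    if (n_events[i] == 3) arms <- c("1p", "1q", "2p")
    sel <- calls$sample_id == sprintf("s%02d", i) & calls$arm %in% arms
    calls$call[sel] <- "del"
  }
  cin <- cin_burden(calls)
  expect_identical(cin$cin_count, as.integer(n_events))
  # brute-force tertile assignment oracle
  cuts <- quantile(n_events, c(1 / 3, 2 / 3), type = 7, names = FALSE)
  oracle <- ifelse(n_events <= cuts[1], "stable",
                   ifelse(n_events <= cuts[2], "medium", "high"))
  expect_identical(cin$cin_class, oracle)
  # monotone in the count
  ord <- order(cin$cin_count)
  ranks <- c(stable = 1, medium = 2, high = 3)
  expect_true(all(diff(ranks[cin$cin_class[ord]]) >= 0))
})

test_that("MATH is the scaled MAD over the median of tumor VAFs", {
  expect_equal(math_score(rep(0.25, 5)), 0)
  expect_equal(math_score(c(0.2, 0.25, 0.3)), 29.652)
  v <- c(0.1, 0.15, 0.22, 0.3)
  expect_equal(math_score(v * 1.8), math_score(v))
  expect_error(math_score(c(0.1, 0.2)), "3")
  expect_error(math_score(c(0, 0, 0)), "zero")
})

test_that("the Lynch rule keys on pathogenic germline-like MMR variants", {
  v <- make_variant(vaf_t = 0.48, gene = "MSH2", pathogenic = TRUE)
  expect_identical(classify_lynch(v, braf_v600e = FALSE), "LS-positive")
  # MLH1-driven cases with BRAF V600E are sporadic MSI-H
  v2 <- make_variant(vaf_t = 0.52, gene = "MLH1", pathogenic = TRUE)
  expect_identical(classify_lynch(v2, braf_v600e = TRUE), "LS-negative")
  expect_identical(classify_lynch(v2, braf_v600e = FALSE), "LS-positive")
  # a non-MLH1 MMR hit still counts despite BRAF
  expect_identical(classify_lynch(rbind(v, v2), braf_v600e = TRUE),
                   "LS-positive")
  # somatic-like VAF or benign variants do not qualify
  expect_identical(classify_lynch(
    make_variant(vaf_t = 0.15, gene = "MSH6", pathogenic = TRUE), FALSE),
    "LS-negative")
  expect_identical(classify_lynch(make_variant(), FALSE), "LS-negative")
  expect_error(classify_lynch(data.frame(gene = "MLH1"), FALSE), "missing")
})

test_that("concordance matches the exact binomial oracle", {
  # all 13 reference positives detected
  res <- concordance(rep(TRUE, 13), rep(TRUE, 13))
  expect_equal(res$ppa, 1)
  expect_equal(res$ppa_ci[1], 0.025^(1 / 13))
  expect_equal(round(100 * res$ppa_ci[1], 1), 75.3)
  expect_equal(res$ppa_ci[2], 1)
  expect_true(is.na(res$npa))

  # none detected: the mirror-image interval
  res0 <- concordance(rep(FALSE, 13), rep(TRUE, 13))
  expect_equal(res0$ppa, 0)
  expect_equal(res0$ppa_ci, c(0, 1 - 0.025^(1 / 13)))

  # interior case against binom.test's Clopper-Pearson interval
  res5 <- concordance(rep(c(TRUE, FALSE), each = 5), rep(TRUE, 10))
  expect_equal(res5$ppa, 0.5)
  expect_equal(res5$ppa_ci,
               as.numeric(binom.test(5, 10)$conf.int), tolerance = 1e-12)
})

test_that("Clopper-Pearson intervals achieve nominal coverage", {
  set.seed(19)
  x <- rbinom(2000, 13, 0.9)
  covered <- vapply(x, function(k) {
    ci <- concordance(c(rep(TRUE, k), rep(FALSE, 13 - k)),
                      rep(TRUE, 13))$ppa_ci
    ci[1] <= 0.9 && 0.9 <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.93)
})
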