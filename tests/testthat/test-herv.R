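test_that("CPM computation matches an elementwise loop oracle", {
  expect_equal(compute_cpm(matrix(5), 1e7)[1, 1], 0.5)
  expect_equal(compute_cpm(matrix(0L), 123)[1, 1], 0)

  set.seed(1)
  counts <- matrix(rpois(200, 40), 20, 10,
                   dimnames = list(paste0("t", 1:20), paste0("s", 1:10)))
  libs <- setNames(sample(1e6:2e6, 10), colnames(counts))
  cpm <- compute_cpm(counts, libs)
  oracle <- counts * NA_real_
  for (i in 1:20) for (j in 1:10)
    oracle[i, j] <- 1e6 * counts[i, j] / libs[j]
  expect_equal(cpm, oracle)

  # scaling counts and library sizes together leaves CPM unchanged
  expect_equal(compute_cpm(counts * 3L, libs * 3), cpm)

  bad <- libs; bad["s4"] <- 0
  expect_error(compute_cpm(counts, bad), "s4")
})

test_that("noise floor zeroes strictly sub-threshold values only", {
  m <- matrix(c(0.49, 0.5, 0.51, 0), 2, 2)
  out <- apply_noise_floor(m, 0.5)
  expect_equal(as.vector(out), c(0, 0.5, 0.51, 0))
  z <- matrix(0, 3, 3)
  expect_equal(apply_noise_floor(z), z)
})

test_that("expression filter keeps median >= 0.1 over tumor samples only", {
  cpm <- rbind(a = c(0, 0, 0.3), b = c(0.1, 0.2, 0.1), c = c(5, 5, 5))
  colnames(cpm) <- paste0("s", 1:3)
  panel <- filter_expressed(cpm, c("a", "b", "c"))
  expect_identical(as.character(panel), c("b", "c"))
  expect_identical(attr(panel, "n_retained"), 2L)

  # only tumor samples enter the median
  cpm2 <- rbind(a = c(9, 9, 0))
  colnames(cpm2) <- paste0("s", 1:3)
  expect_identical(
    as.character(filter_expressed(cpm2, "a", is_tumor = c(F, F, T))),
    character(0))
  expect_error(filter_expressed(cpm, "a", is_tumor = rep(FALSE, 3)),
               "tumor")
})

test_that("silent loci planted by the generator are exactly the ones removed", {
  e <- simulate_expression(sim_config(seed = 2L, n_samples = 30L))
  cpm <- apply_noise_floor(compute_cpm(e$counts, e$library_sizes))
  panel <- filter_expressed(cpm, e$herv_panel)
  expect_setequal(panel, names(e$truth$silent)[!e$truth$silent])
})

test_that("median.hERV uses the midpoint-average median and scales linearly", {
  cpm <- matrix(c(0, 1, 2), 3, 1, dimnames = list(letters[1:3], "s1"))
  expect_equal(median_herv(cpm, letters[1:3])$median_herv, 1)
  cpm2 <- matrix(c(1, 3), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(median_herv(cpm2, c("a", "b"))$median_herv, 2)
  expect_error(median_herv(cpm, character(0)), "empty")

  set.seed(3)
  m <- matrix(rexp(50), 10, 5,
              dimnames = list(paste0("t", 1:10), paste0("s", 1:5)))
  expect_equal(median_herv(m * 3.7, rownames(m))$median_herv,
               3.7 * median_herv(m, rownames(m))$median_herv)
})

test_that("high-cluster samples have larger median.hERV (one-sided U-test)", {
  e <- simulate_expression(sim_config(seed = 4L, n_samples = 60L))
  cpm <- apply_noise_floor(compute_cpm(e$counts, e$library_sizes))
  panel <- filter_expressed(cpm, e$herv_panel)
  mh <- median_herv(cpm, panel)
  hi <- mh$median_herv[e$truth$cluster == "high"]
  lo <- mh$median_herv[e$truth$cluster == "low"]
  expect_lt(wilcox.test(hi, lo, alternative = "greater")$p.value, 0.01)
})

test_that("the pipeline stage order is load-bearing", {
  # a transcript whose values sit between the two thresholds flips fate if
  # the expression filter runs before the noise floor
  cpm <- matrix(c(0.3, 0.3, 0.3), 1, 3,
                dimnames = list("t1", paste0("s", 1:3)))
  after_floor <- filter_expressed(apply_noise_floor(cpm), "t1")
  before_floor <- filter_expressed(cpm, "t1")
  expect_length(after_floor, 0)
  expect_length(before_floor, 1)
})

test_that("downsampling at fraction 1 is the identity and seeds reproduce", {
  e <- simulate_expression(small_cfg(seed = 6L))
  cpm <- apply_noise_floor(compute_cpm(e$counts, e$library_sizes))
  panel <- filter_expressed(cpm, e$herv_panel)
  full <- downsampling_robustness(cpm, panel, fraction = 1, rounds = 5,
                                  seed = 9L)
  expect_true(all(full$spearman == 1))
  a <- downsampling_robustness(cpm, panel, rounds = 10, seed = 5L)
  b <- downsampling_robustness(cpm, panel, rounds = 10, seed = 5L)
  expect_identical(a$scores, b$scores)
  expect_error(downsampling_robustness(cpm, panel[1], seed = 1L),
               "at least 2")
})

test_that("two-cluster labels are order-invariant and honor the contract", {
  e <- simulate_expression(sim_config(seed = 8L, n_samples = 40L))
  cpm <- apply_noise_floor(compute_cpm(e$counts, e$library_sizes))
  panel <- filter_expressed(cpm, e$herv_panel)
  lab <- cluster_two(cpm, panel)

  perm <- sample(ncol(cpm))
  lab_perm <- cluster_two(cpm[, perm], panel)
  expect_identical(lab_perm[names(lab)], lab)

  mh <- median_herv(cpm, panel)
  expect_gte(median(mh$median_herv[lab == "high"]),
             median(mh$median_herv[lab == "low"]))

  flat <- matrix(1, length(panel), 6,
                 dimnames = list(panel, paste0("s", 1:6)))
  expect_error(cluster_two(flat, panel), "identical")
})

test_that("top-fraction dichotomization matches a hand quantile oracle", {
  expect_identical(which(dichotomize_top_fraction(1:10, 0.30)), 8:10)
  expect_identical(sum(dichotomize_top_fraction(c(5, 5, 5, 1), 0.30)), 3L)
  expect_warning(out <- dichotomize_top_fraction(rep(2, 5)), "identical")
  expect_true(all(out))
  expect_error(dichotomize_top_fraction(3), "finite")

  set.seed(10)
  for (i in 1:200) {
    v <- runif(sample(5:80, 1)) * 10
    f <- runif(1, 0.05, 0.95)
    x <- sort(v)
    h <- (length(x) - 1) * (1 - f) + 1
    thr <- x[floor(h)] + (h - floor(h)) * (x[ceiling(h)] - x[floor(h)])
    expect_identical(dichotomize_top_fraction(v, f), v >= thr)
  }
})
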