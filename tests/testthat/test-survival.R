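test_that("OS and RFS come from the dated intervals in months", {
  frame <- data.frame(id = c("p1", "p2"),
                      date_diagnosis = c(0, 0),
                      date_surgery = c(0, 30),
                      date_endpoint = c(0, 639),
                      death_event = c(0, 1),
                      relapse_event = c(0, 1))
  st <- compute_survival_times(frame)
  expect_equal(st$os_months[1], 0)
  expect_equal(round(st$rfs_months[2], 1), 20.0)   # 609 days
  expect_equal(st$os_months[2], 639 / 30.4375)

  bad <- frame; bad$date_endpoint[2] <- 20       # endpoint before surgery
  expect_error(compute_survival_times(bad), "p2")
  nodate <- frame; nodate$date_surgery[1] <- NA
  expect_error(compute_survival_times(nodate), "p1")
})

test_that("WTS grouping reproduces the full 2x2 truth table", {
  cd8 <- c(1, 1, 10, 10)
  herv <- c(1, 10, 1, 10)
  g <- assign_wts_group(cd8, herv)
  expect_identical(g$cd8_high, c(FALSE, FALSE, TRUE, TRUE))
  expect_identical(g$herv_high, c(FALSE, TRUE, FALSE, TRUE))
  expect_identical(g$wts_group, c("WTS+", "WTS-", "WTS+", "WTS+"))
  # label set is order-independent
  perm <- c(3, 1, 4, 2)
  expect_identical(assign_wts_group(cd8[perm], herv[perm])$wts_group,
                   g$wts_group[perm])
  expect_error(assign_wts_group(cd8, herv[1:3]), "length")
})

test_that("CP grouping flags any unfavorable factor", {
  age <- c(50, 52, 54, 56, 58, 60, 62, 64, 66, 90)
  stage <- rep("II", 10)
  side <- rep("left", 10)
  base <- assign_cp_group(age, stage, side)
  expect_identical(base[1], "CP+")
  expect_identical(base[10], "CP-")       # top-30% age
  side2 <- side; side2[1] <- "right"
  expect_identical(assign_cp_group(age, stage, side2)[1], "CP-")
  stage3 <- stage; stage3[1] <- "III"
  expect_identical(assign_cp_group(age, stage3, side)[1], "CP-")
  miss <- side; miss[2] <- NA
  expect_warning(out <- assign_cp_group(age, stage, miss), "missing")
  expect_true(is.na(out[2]))
})

test_that("log-rank is exactly null on duplicated groups", {
  times <- c(3, 5, 7, 9, 11)
  events <- c(1, 0, 1, 1, 0)
  fit <- km_logrank(c(times, times), c(events, events),
                    rep(c("A", "B"), each = 5))
  expect_lt(abs(fit$logrank_stat), 1e-9)
  expect_equal(fit$logrank_p, 1, tolerance = 1e-6)
})

test_that("log-rank matches a hand-built risk table on six patients", {
  times <- 1:6
  events <- rep(1L, 6)
  groups <- rep(c("A", "B"), 3)
  # hand computation: at each event time, O - E and hypergeometric variance
  at_risk_A <- o_minus_e <- v <- numeric(6)
  nA <- 3; nB <- 3
  for (t in 1:6) {
    n <- nA + nB
    dA <- as.integer(t %% 2 == 1)   # A dies at odd times
    e <- nA / n                     # one death per time
    o_minus_e[t] <- dA - e
    v[t] <- (nA * nB) / n^2         # d(n-d)(..)/(n^2(n-1)) with d=1
    if (dA == 1) nA <- nA - 1 else nB <- nB - 1
  }
  stat_hand <- sum(o_minus_e)^2 / sum(v)
  fit <- km_logrank(times, events, groups)
  expect_equal(fit$logrank_stat, stat_hand, tolerance = 1e-12)
})

test_that("KM curves are proper survivor functions", {
  set.seed(23)
  times <- rexp(40, 1 / 20)
  fit <- km_logrank(c(times, times), rep(1L, 80),
                    rep(c("A", "B"), each = 40))
  s <- summary(fit$survfit)
  expect_true(all(diff(s$surv[s$strata == s$strata[1]]) <= 0))
  # with no censoring the KM curve equals the empirical survivor function
  sA <- s$surv[s$strata == s$strata[1]]
  tA <- s$time[s$strata == s$strata[1]]
  emp <- sapply(tA, function(t) mean(times > t))
  expect_equal(sA, emp, tolerance = 1e-12)
  expect_error(km_logrank(times, rep(1, 40), rep("A", 40)), "2")
})

test_that("a two-patient-per-arm Cox fixture matches the hand solution", {
  # four patients, one binary covariate, no ties: the partial likelihood
  # can be maximized by direct 1-d Newton iteration
  times <- c(1, 2, 3, 4)
  events <- rep(1L, 4)
  x <- c(1, 0, 1, 0)
  loglik <- function(b) {
    risk <- exp(b * x)
    sum(sapply(which(events == 1), function(i) {
      at <- times >= times[i]
      b * x[i] - log(sum(risk[at]))
    }))
  }
  b <- stats::optimize(loglik, c(-5, 5), maximum = TRUE,
                       tol = 1e-10)$maximum
  fit <- cox_fit(times, events, data.frame(x = x), "univariate")
  expect_equal(log(fit$hr), b, tolerance = 1e-4)
})

test_that("Cox null covariates keep nominal coverage and constants error", {
  set.seed(29)
  cover <- mean(sapply(1:200, function(i) {
    t <- rexp(50, 1 / 30)
    x <- rnorm(50)
    fit <- cox_fit(t, rep(1L, 50), data.frame(x = x), "univariate")
    fit$ci_lower <= 1 && 1 <= fit$ci_upper
  }))
  expect_gte(cover, 0.93)
  expect_error(cox_fit(rexp(10), rep(1, 10),
                       data.frame(k = rep(1, 10))), "constant")
})

test_that("multivariate mode needs more events than covariates", {
  d <- data.frame(a = rnorm(10), b = rnorm(10), c = rnorm(10))
  expect_error(cox_fit(rexp(10), rep(c(1L, 0L), c(2, 8)), d,
                       "multivariate"), "events")
})

test_that("enrichment test matches the hypergeometric tail oracle", {
  equal <- enrichment_test(rep(c("x", "y"), each = 50),
                           rep(rep(c(TRUE, FALSE), c(10, 40)), 2))
  expect_equal(equal$p, 1)

  a <- rep(c("x", "y"), each = 10)
  b <- c(rep(TRUE, 9), FALSE, TRUE, rep(FALSE, 9))
  res <- enrichment_test(a, b)
  # two-sided Fisher p: sum of hypergeometric probabilities of all tables
  # as or more extreme than the observed [[9,1],[1,9]]
  probs <- dhyper(0:10, 10, 10, 10)
  p_hand <- sum(probs[probs <= dhyper(9, 10, 10, 10) + 1e-12])
  expect_equal(res$p, p_hand, tolerance = 1e-12)
  # symmetric under swapping groups
  swap <- enrichment_test(ifelse(a == "x", "y", "x"), b)
  expect_equal(swap$p, res$p)
  # empty category returns NA
  expect_true(is.na(enrichment_test(rep("x", 10), b[1:10])$p))
})
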